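# Fixtures built in code: tiny instruments, hand-sized response tables and
# toy networks shared across the suite.

toy_instrument <- function(name = "toy", k = 3L) {
  instrument(name, paste0(substr(name, 1, 1), seq_len(k)),
             severity_bands = data.frame(
               band = c("low", "high"),
               lo = c(0L, as.integer(ceiling(3 * k / 2))),
               hi = c(as.integer(ceiling(3 * k / 2)) - 1L, 3L * k)))
}

# complete 0..3 table over PHQ-9 + GAD-7 columns
full_raw_table <- function(n = 5L, seed = 42L) {
  set.seed(seed)
  items <- c(paste0("D", 1:9), paste0("A", 1:7))
  as.data.frame(matrix(sample(0:3, n * 16, replace = TRUE), n,
                       dimnames = list(NULL, items)))
}

toy_item_matrix <- function(values, communities = NULL) {
  if (is.null(communities)) {
    k <- ncol(values)
    comm <- if (k < 4) rep("c1", k) else
      c(rep("c1", ceiling(k / 2)), rep("c2", k - ceiling(k / 2)))
    communities <- setNames(comm, colnames(values))
  }
  item_matrix(values, communities = communities)
}

# 3-node toy network: AB = 0.5, AC = -0.2
toy_net3 <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["A", "C"] <- W["C", "A"] <- -0.2
  symptom_network(W, communities = c(A = "x", B = "x", C = "y"))
}

# weight matrix helper
net_from_edges <- function(labels, edges, communities = NULL) {
  W <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (e in edges) {
    W[e[[1]], e[[2]]] <- W[e[[2]], e[[1]]] <- e[[3]]
  }
  symptom_network(W, communities = communities)
}

small_cohort <- function(n = 400L, seed = 5L, ...) {
  sample_cohort(generator_spec(n_subjects = n, seed = seed, ...))
}
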
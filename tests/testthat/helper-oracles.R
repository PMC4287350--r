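# Independent oracles and small in-code fixtures shared across tests.

# Plain (unadjusted) Rand index between two labelings.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  concordant <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    concordant <- concordant + ((a[i] == a[j]) == (b[i] == b[j]))
  concordant / choose(n, 2)
}

# Brute-force PWM p-value: enumerate all 4^w words, weight by background.
enumerate_pwm_pvalue <- function(motif, score) {
  lo <- log2(motif$pwm / motif$background[rownames(motif$pwm)])
  w <- ncol(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  word_scores <- numeric(nrow(words))
  word_probs <- rep(1, nrow(words))
  for (j in seq_len(w)) {   # column-by-column, like a word is scored
    word_scores <- word_scores + lo[words[, j], j]
    word_probs <- word_probs * motif$background[words[, j]]
  }
  vapply(score, function(s) sum(word_probs[word_scores >= s - 1e-9]),
         numeric(1))
}

# A random PWM over a random background, for oracle-equivalence loops.
random_pwm <- function(width, seed) {
  set.seed(seed)
  mat <- matrix(stats::rgamma(4 * width, shape = 1), nrow = 4)
  mat <- sweep(mat, 2, colSums(mat), "/")
  bg <- stats::rgamma(4, shape = 2)
  motif_model(paste0("rand", seed), pwm = mat, window = c(-100, -1),
              background = bg / sum(bg))
}

# Hand-built annotation used by the context-category tests:
#   cdsA 1000-2000 +, cdsB 2150-3000 +, cdsC 2100-2250 - (gap overlap),
#   cdsD 5000-6000 -, operon cdsA->cdsB.
toy_annotation <- function() {
  cds <- data.frame(
    id = c("cdsA", "cdsB", "cdsC", "cdsD"),
    start = c(1000, 2150, 2100, 5000),
    end = c(2000, 3000, 2250, 6000),
    strand = c("+", "+", "-", "-"),
    stringsAsFactors = FALSE)
  genome_annotation(cds, operons = list(op1 = c("cdsA", "cdsB")),
                    genome_length = 10000, ori = 1, ter = 5000)
}

# Small generator config that keeps simulation-heavy tests fast.
small_config <- function(seed = 11, ...) {
  generator_config(genome_length = 90000, n_cds = 45, n_operons = 4,
                   n_true_tss = 60, n_processing_sites = 15, seed = seed,
                   ...)
}

# 8-point cosine profile m * exp(A cos(2 pi (t - phase)/160)).
cosine_profile <- function(m, A, phase) {
  t <- seq(0, 140, by = 20)
  m * exp(A * cos(2 * pi * (t - phase) / 160))
}
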
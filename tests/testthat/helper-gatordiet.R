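# Shared fixtures and independent oracles for the test suite.

# random non-degenerate count matrix (every row holds >= 1 item)
random_count_matrix <- function(nr = sample(2:10, 1), nc = sample(2:8, 1),
                                lambda = 1.2) {
  m <- matrix(stats::rpois(nr * nc, lambda), nr, nc)
  for (i in which(rowSums(m) == 0)) m[i, sample(nc, 1)] <- 1L
  storage.mode(m) <- "integer"
  m
}

# brute-force Shannon mutual information between row identity (weighted by
# row totals) and column category, summed cell by cell -- independent of the
# package's entropy-difference / KL formulation
oracle_mutual_information <- function(counts) {
  N <- sum(counts)
  p <- counts / N
  pr <- rowSums(p)
  pc <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
    }
  }
  mi
}

# literal transcription of the two prey-importance equations:
# IRI_j = FO_j * (N_j + W_j), %IRI_j = IRI_j / sum(IRI)
oracle_pct_iri <- function(counts, masses) {
  fo <- apply(counts > 0, 2, sum) / nrow(counts)
  pn <- apply(counts, 2, sum) / sum(counts)
  pw <- apply(masses, 2, sum) / sum(masses)
  iri <- fo * (pn + pw)
  iri / sum(iri)
}

# wrap plain count/mass matrices as a diet_matrix (column labels need not
# span the vocabulary; only matrix-level operations consume these)
dm <- function(counts, masses = counts) {
  counts <- as.matrix(counts)
  masses <- as.matrix(masses)
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    rownames(counts) <- rownames(masses) <- paste0("ind", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    colnames(counts) <- colnames(masses) <-
      prey_categories()[seq_len(ncol(counts))]
  }
  structure(list(counts = counts, masses = masses), class = "diet_matrix")
}

# tiny in-code dataset: three individuals, four prey rows
demo_dataset <- function() {
  individuals <- data.frame(
    individual_id = c("a1", "a2", "a3"),
    population = "demo",
    capture_date = as.Date(c("2019-06-01", "2019-06-02", "2019-07-15")),
    total_length_cm = c(120.5, 95.0, 150.2),
    snout_vent_length_cm = c(60.1, 47.5, NA),
    sex = c("M", "F", "unknown"),
    capture_salinity_ppt = c(0.5, NA, 12.0),
    recapture = FALSE,
    stringsAsFactors = FALSE
  )
  observations <- data.frame(
    individual_id = c("a1", "a1", "a2", "a3"),
    prey_category = c("crustaceans", "insects_arachnids", "fishes",
                      "crustaceans"),
    item_count = c(2L, 5L, 1L, 3L),
    wet_mass_g = c(5.0, 1.5, 8.2, 7.1),
    stringsAsFactors = FALSE
  )
  diet_dataset(individuals, observations)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "gatordiet", mustWork = TRUE)
}
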
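# Shared toy data builders and independent oracles. Every oracle here is
# deliberately naive (enumeration, hand arithmetic) and never calls the code
# path it checks.

tiny_table <- function() {
  m <- matrix(c(5, 0, 1, 0, 2, 2), nrow = 3,
              dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
  feature_table(m)
}

random_table <- function(n_samples, n_taxa, max_count = 50) {
  m <- matrix(sample(0:max_count, n_samples * n_taxa, replace = TRUE),
              nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  m[, colSums(m) == 0] <- 1L   # avoid degenerate zero-total samples
  feature_table(m)
}

# metadata for one donor + recipients sampled at the given timepoints
toy_metadata <- function(subjects, arms, timepoints, donor_ids = "DON1") {
  recip <- expand.grid(subject_id = subjects, timepoint = timepoints,
                       stringsAsFactors = FALSE)
  recip$arm <- arms[match(recip$subject_id, subjects)]
  recip$role <- "recipient"
  recip$donor_id <- ifelse(recip$arm == "FMT", donor_ids[1], NA_character_)
  recip$sample_id <- paste0(recip$subject_id, "_", recip$timepoint)
  don <- data.frame(sample_id = paste0(donor_ids, "_donor"),
                    subject_id = donor_ids, role = "donor", arm = "none",
                    timepoint = "donor", donor_id = NA_character_)
  sample_metadata(rbind(recip[names(don)], don))
}

# -- oracles ------------------------------------------------------------------

# Bray-Curtis on relative abundances, written out longhand
oracle_bray <- function(x, y) {
  px <- x / sum(x); py <- y / sum(y)
  sum(abs(px - py)) / sum(px + py)
}

# unweighted UniFrac by explicit branch enumeration over an ape tree
oracle_unifrac <- function(tree, leaves_a, leaves_b) {
  n_tip <- length(tree$tip.label)
  descendants <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descendants))
  }
  unique_len <- 0; union_len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    desc <- descendants(tree$edge[e, 2])
    in_a <- any(desc %in% leaves_a)
    in_b <- any(desc %in% leaves_b)
    len <- tree$edge.length[e]
    if (in_a || in_b) union_len <- union_len + len
    if (xor(in_a, in_b)) unique_len <- unique_len + len
  }
  unique_len / union_len
}

# ANOSIM R statistic from first principles (ranked dissimilarities)
oracle_anosim_r <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])
  within <- groups[idx[, 1]] == groups[idx[, 2]]
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# exact ANOSIM p by exhaustive enumeration of distinct label permutations
oracle_anosim_p <- function(d, groups) {
  n <- length(groups)
  perms <- combinat_perms(seq_len(n))
  r_obs <- oracle_anosim_r(d, groups)
  r_all <- apply(perms, 1, function(p) oracle_anosim_r(d, groups[p]))
  mean(r_all >= r_obs - 1e-12)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- combinat_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# two-sided Fisher p by brute-force hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kaplan-Meier product-limit values computed longhand at event times
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  s <- 1; out <- numeric(0); times <- unique(time[event == 1])
  for (t in times) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  data.frame(time = times, survival = out)
}
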
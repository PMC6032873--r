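# shared in-code fixtures and independent oracles

# Hamming mismatch fraction between two equal-length sequences, computed
# independently of any package internals
hamming_frac <- function(a, b) {
  mean(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# build a record data.frame directly
rec <- function(id, seq, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Q40
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

qual_chr <- function(scores) rawToChar(as.raw(scores + 33L))

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# reverse complement, independent of the package implementation
rc <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# small hand-built hit table for consensus tests
hit_table <- function(species, genus, family, score = 100) {
  n <- length(species)
  data.frame(ref_id = sprintf("r%d", seq_len(n)), species = species,
             genus = genus, family = family,
             score = rep_len(score, n),
             bit_score = (1.28 * rep_len(score, n) - log(0.46)) / log(2),
             stringsAsFactors = FALSE)
}

# tidy profile table row helper
profile_rows <- function(insect_id, taxa, counts,
                         insect_species = "E_pertinax", sex = "F",
                         site = "S1", period = "early") {
  data.frame(insect_id = insect_id, insect_species = insect_species,
             sex = sex, site = site, period = period, taxon = taxa,
             count = counts, percent = 100 * counts / sum(counts),
             stringsAsFactors = FALSE)
}

# plain logistic regression by hand-rolled IRLS: the independent oracle for
# the variance-constrained mixed model
irls_logistic <- function(X, y, tol = 1e-10, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  beta
}

# simulate visitor-classification data from a known crossed random-intercept
# logistic model (4 sites, 6 species)
sim_glmm_data <- function(n, beta0 = -0.4, beta_period = 1, beta_sex = 0,
                          site_sd = 0.5, species_sd = 0.5, seed = 1) {
  set.seed(seed)
  sites <- paste0("S", 1:4)
  species <- paste0("sp", 1:6)
  d <- data.frame(
    period = sample(c("early", "late"), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = sample(sites, n, replace = TRUE),
    species = sample(species, n, replace = TRUE),
    stringsAsFactors = FALSE)
  u_site <- setNames(rnorm(4, 0, site_sd), sites)
  u_sp <- setNames(rnorm(6, 0, species_sd), species)
  eta <- beta0 + beta_period * (d$period == "late") +
    beta_sex * (d$sex == "M") + u_site[d$site] + u_sp[d$species]
  d$visitor_class <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "single", "multi")
  d
}

# all compositions of `total` into `k` nonnegative parts (enumeration oracle
# for the minimum-KL integer allocation)
compositions_of <- function(total, k) {
  if (k == 1) return(list(total))
  out <- list()
  for (x in 0:total)
    for (rest in compositions_of(total - x, k - 1))
      out[[length(out) + 1L]] <- c(x, rest)
  out
}
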
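#' Default hoverfly species pool with capture weights
#'
#' Six *Eristalis* species with relative capture weights reflecting the uneven
#' species frequencies typical of grassland hand-netting surveys (the rarest
#' species contribute only a couple of individuals, the commonest dozens).
#'
#' @return Named numeric vector of sampling weights (they need not sum to 1).
#' @export
eristalis_pool <- function() {
  c(E_arbustorum = 5, E_horticola = 57, E_intricaria = 2,
    E_nemorum = 41, E_pertinax = 53, E_tenax = 17)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability `rate`, drawing the new
# base uniformly from the three alternatives
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    bases[hit] <- vapply(bases[hit], function(b) {
      i <- sample.int(3L, 1L)
      substr(alt[[b]], i, i)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(bases, collapse = "")
}

#' Generate a hierarchically structured reference sequence library
#'
#' Evolves species sequences from a single random root along a
#' family/genus/species hierarchy by independent substitutions. Branch rates
#' are chosen so that two species of the same genus differ in expectation by
#' roughly the within-genus divergence, and species of different genera by at
#' least the (larger) between-genus divergence.
#'
#' @param n_families Number of families.
#' @param genera_per_family Genera per family.
#' @param species_per_genus Species per genus.
#' @param divergence List with elements `within_genus` and `between_genus`,
#'   expected pairwise substitution fractions; `within_genus` must not exceed
#'   `between_genus`, both in `[0, 1)`.
#' @param seq_length Reference sequence length in bases (default 500, the
#'   length of the amplicon used throughout).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An object of class `taxonomy_truth`: list with `taxa` (data.frame
#'   `species_id`, `genus_id`, `family_id`), `sequences` (named character
#'   vector, names = species ids) and `divergence`.
#' @export
generate_reference_db <- function(n_families, genera_per_family,
                                  species_per_genus,
                                  divergence = list(within_genus = 0.05,
                                                    between_genus = 0.15),
                                  seq_length = 500, seed = NULL) {
  stopifnot(n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
            seq_length >= 1)
  w <- divergence$within_genus
  b <- divergence$between_genus
  if (is.null(w) || is.null(b) || w < 0 || b < 0 || w >= 1 || b >= 1)
    stop("divergence values must lie in [0, 1)")
  if (w > b)
    stop("within-genus divergence must not exceed between-genus divergence")
  if (!is.null(seed)) set.seed(seed)

  root <- rand_dna(seq_length)
  taxa <- list()
  seqs <- character(0)
  for (f in seq_len(n_families)) {
    fam_id <- sprintf("fam%02d", f)
    fam_anc <- mutate_seq(root, b / 2)
    for (g in seq_len(genera_per_family)) {
      gen_id <- sprintf("%s_gen%02d", fam_id, g)
      gen_anc <- mutate_seq(fam_anc, b / 2)
      for (s in seq_len(species_per_genus)) {
        sp_id <- sprintf("%s_sp%02d", gen_id, s)
        taxa[[length(taxa) + 1L]] <- data.frame(
          species_id = sp_id, genus_id = gen_id, family_id = fam_id,
          stringsAsFactors = FALSE)
        seqs[[sp_id]] <- mutate_seq(gen_anc, w / 2)
      }
    }
  }
  structure(list(taxa = do.call(rbind, taxa), sequences = seqs,
                 divergence = list(within_genus = w, between_genus = b)),
            class = "taxonomy_truth")
}

#' Write a reference library as FASTA with three-rank headers
#'
#' Headers follow the convention `>species_id|genus_id|family_id` expected by
#' [build_reference_index()].
#'
#' @param db A `taxonomy_truth` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  stopifnot(inherits(db, "taxonomy_truth"))
  headers <- sprintf("%s|%s|%s", db$taxa$species_id, db$taxa$genus_id,
                     db$taxa$family_id)
  x <- Biostrings::DNAStringSet(db$sequences[db$taxa$species_id])
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Generate ground-truth per-insect pollen mixtures
#'
#' With probability `specialist_prob` an insect is a near-pure single-taxon
#' carrier ("specialist"): its dominant taxon is drawn proportional to
#' `availability` and its dominant proportion from a Beta(20, 1) truncated to
#' at least `specialist_floor`, with the remainder spread over up to three
#' other available taxa. Otherwise ("generalist") proportions are drawn from a
#' symmetric Dirichlet over 2–6 taxa sampled proportional to `availability`.
#'
#' The default specialist fraction is period-dependent (0.40 early, 0.24
#' late), emulating the seasonal decline of flower constancy in grassland
#' hoverflies.
#'
#' @param n Number of insects.
#' @param site Site label.
#' @param period `"early"` or `"late"`.
#' @param availability Named nonnegative numeric vector of plant availability
#'   over plant species ids; must contain at least one positive entry.
#' @param specialist_prob Probability an insect is a specialist; `NULL`
#'   (default) selects 0.40 for early and 0.24 for late.
#' @param concentration Symmetric Dirichlet concentration for generalist
#'   mixtures (default 1).
#' @param specialist_floor Minimum dominant proportion for specialists
#'   (default 0.9).
#' @param species_pool Named weights for insect species sampling
#'   (default [eristalis_pool()]).
#' @param seed Optional integer seed.
#' @return Object of class `synthetic_mixtures`: list with `insects`
#'   (data.frame `insect_id`, `insect_species`, `sex`, `site`, `period`,
#'   `specialist`) and `proportions` (data.frame `insect_id`, `species_id`,
#'   `proportion`; proportions per insect sum to 1).
#' @export
generate_insects <- function(n, site, period,
                             availability,
                             specialist_prob = NULL,
                             concentration = 1,
                             specialist_floor = 0.9,
                             species_pool = eristalis_pool(),
                             seed = NULL) {
  period <- match.arg(period, c("early", "late"))
  if (is.null(specialist_prob))
    specialist_prob <- if (period == "early") 0.40 else 0.24
  stopifnot(specialist_prob >= 0, specialist_prob <= 1)
  if (length(availability) == 0 || all(availability <= 0))
    stop("availability must contain at least one positive entry")
  if (is.null(names(availability)))
    stop("availability must be named by plant species id")
  if (!is.null(seed)) set.seed(seed)
  avail <- availability[availability > 0]

  rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }

  insects <- vector("list", n)
  props <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("%s_%s_ins%03d", site, period, i)
    spp <- sample(names(species_pool), 1L, prob = species_pool)
    sex <- sample(c("F", "M"), 1L)
    is_spec <- runif(1) < specialist_prob
    if (is_spec) {
      main <- sample(names(avail), 1L, prob = avail)
      # Beta(20,1) truncated to >= specialist_floor by rejection
      repeat {
        p_main <- stats::rbeta(1, 20, 1)
        if (p_main >= specialist_floor) break
      }
      others <- setdiff(names(avail), main)
      k <- min(length(others), sample.int(3L, 1L))
      if (k > 0 && p_main < 1) {
        minor <- sample(others, k, prob = avail[others])
        rest <- rdirichlet1(rep(1, k)) * (1 - p_main)
        pp <- c(setNames(p_main, main), setNames(rest, minor))
      } else {
        pp <- setNames(1, main)
      }
    } else {
      k <- sample(2:min(6L, length(avail)), 1L)
      chosen <- sample(names(avail), k, prob = avail)
      pp <- setNames(rdirichlet1(rep(concentration, k)), chosen)
    }
    pp <- pp / sum(pp)
    insects[[i]] <- data.frame(insect_id = id, insect_species = spp, sex = sex,
                               site = site, period = period,
                               specialist = is_spec, stringsAsFactors = FALSE)
    props[[i]] <- data.frame(insect_id = id, species_id = names(pp),
                             proportion = unname(pp), stringsAsFactors = FALSE)
  }
  structure(list(insects = do.call(rbind, insects),
                 proportions = do.call(rbind, props)),
            class = "synthetic_mixtures")
}

#' Read-simulation configuration
#'
#' @param read_length Read length in bases (default 300, 2x300 style).
#' @param amplicon_length Amplicon length (default 500 so merged reads pass
#'   the >450 bp length filter).
#' @param depth Fixed per-insect read-pair count, or `NULL` to draw depths
#'   from a lognormal distribution.
#' @param depth_meanlog,depth_sdlog Lognormal depth parameters used when
#'   `depth` is `NULL` (defaults `log(200)` and 0.6).
#' @param error_rate Per-base substitution error probability in `[0, 0.25]`.
#' @param base_quality Constant Phred quality written for simulated bases.
#' @param short_fraction Fraction of insects whose amplicon is truncated to
#'   `short_length` bases, to exercise the merged-length filter (default 0).
#' @param short_length Truncated amplicon length (default 430).
#' @return List of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 300, amplicon_length = 500,
                            depth = NULL,
                            depth_meanlog = log(200), depth_sdlog = 0.6,
                            error_rate = 0.005, base_quality = 40,
                            short_fraction = 0, short_length = 430) {
  if (error_rate < 0 || error_rate > 0.25)
    stop("error_rate must lie in [0, 0.25]")
  if (!is.null(depth) && depth < 0) stop("depth must be >= 0")
  if (read_length > amplicon_length)
    stop("read_length must not exceed amplicon_length")
  if (short_fraction > 0 && read_length > short_length)
    stop("read_length must not exceed short_length")
  structure(list(read_length = read_length,
                 amplicon_length = amplicon_length,
                 depth = depth, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, error_rate = error_rate,
                 base_quality = base_quality,
                 short_fraction = short_fraction,
                 short_length = short_length),
            class = "read_sim_config")
}

# vectorised substitution errors: most reads carry none at typical rates, so
# draw per-read error counts first and only edit the affected reads
add_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  seqs <- unname(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      b <- substr(seqs[i], p, p)
      j <- sample.int(3L, 1L)
      substr(seqs[i], p, p) <- substr(alt[[b]], j, j)
    }
  }
  seqs
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired-end amplicon reads from pollen mixtures
#'
#' For each insect, per-read source taxa are sampled from the true mixture
#' proportions; the forward read is the first `read_length` bases of the
#' source amplicon and the reverse read the reverse complement of its last
#' `read_length` bases; substitution errors are applied i.i.d. per base.
#' The error model is substitution-only (no indels), so merged-read lengths
#' are deterministic given the amplicon length.
#'
#' @param mixtures A `synthetic_mixtures` object.
#' @param taxonomy A `taxonomy_truth` object covering every mixture taxon.
#' @param config A [read_sim_config()].
#' @param seed Optional integer seed.
#' @return List with `fwd` and `rev` (record data.frames as returned by
#'   [read_fastq()]: columns `id`, `seq`, `qual`) and `truth` (data.frame
#'   `read_id`, `insect_id`, `species_id`).
#' @export
generate_reads <- function(mixtures, taxonomy, config = read_sim_config(),
                           seed = NULL) {
  stopifnot(inherits(mixtures, "synthetic_mixtures"),
            inherits(taxonomy, "taxonomy_truth"),
            inherits(config, "read_sim_config"))
  missing_taxa <- setdiff(mixtures$proportions$species_id,
                          names(taxonomy$sequences))
  if (length(missing_taxa))
    stop("mixture taxa absent from taxonomy: ",
         paste(missing_taxa, collapse = ", "))
  if (any(nchar(taxonomy$sequences) < config$amplicon_length))
    stop("reference sequences shorter than amplicon_length")
  if (!is.null(seed)) set.seed(seed)

  fwd <- list(); rev <- list(); truth <- list()
  for (ins in mixtures$insects$insect_id) {
    pp <- mixtures$proportions[mixtures$proportions$insect_id == ins, ]
    depth <- if (!is.null(config$depth)) config$depth else
      max(0L, round(rlnorm(1, config$depth_meanlog, config$depth_sdlog)))
    if (depth == 0) next
    amp_len <- if (config$short_fraction > 0 &&
                   runif(1) < config$short_fraction)
      config$short_length else config$amplicon_length
    src <- sample(pp$species_id, depth, replace = TRUE, prob = pp$proportion)
    amplicons <- substr(taxonomy$sequences[src], 1L, amp_len)
    f <- substr(amplicons, 1L, config$read_length)
    r <- revcomp_chr(substr(amplicons, amp_len - config$read_length + 1L,
                            amp_len))
    f <- add_substitutions(f, config$error_rate)
    r <- add_substitutions(r, config$error_rate)
    ids <- sprintf("%s_read%05d", ins, seq_len(depth))
    qual <- strrep(rawToChar(as.raw(config$base_quality + 33L)),
                   config$read_length)
    fwd[[ins]] <- data.frame(id = ids, seq = f, qual = qual,
                             stringsAsFactors = FALSE)
    rev[[ins]] <- data.frame(id = ids, seq = r, qual = qual,
                             stringsAsFactors = FALSE)
    truth[[ins]] <- data.frame(read_id = ids, insect_id = ins,
                               species_id = unname(src),
                               stringsAsFactors = FALSE)
  }
  empty_rec <- data.frame(id = character(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE)
  list(fwd = if (length(fwd)) do.call(rbind, c(fwd, make.row.names = FALSE)) else empty_rec,
       rev = if (length(rev)) do.call(rbind, c(rev, make.row.names = FALSE)) else empty_rec,
       truth = if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE)) else
         data.frame(read_id = character(0), insect_id = character(0),
                    species_id = character(0), stringsAsFactors = FALSE))
}

#' Simulate a quadrat flower survey
#'
#' Draws per-quadrat floral-unit counts for each available plant species from
#' a Poisson whose mean is proportional to availability, emulating the
#' 30-quadrat flower-resource survey carried out once per site and period.
#'
#' @param site,period Labels attached to the survey records.
#' @param availability Named nonnegative availability vector.
#' @param n_quadrats Number of 1-m2 quadrats (default 30).
#' @param mean_units_per_quadrat Expected total floral units per quadrat.
#' @param seed Optional integer seed.
#' @return Data.frame `site`, `period`, `quadrat_id`, `plant_species`,
#'   `floral_units`.
#' @export
generate_flower_survey <- function(site, period, availability,
                                   n_quadrats = 30,
                                   mean_units_per_quadrat = 5,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  avail <- availability / sum(availability)
  out <- list()
  for (q in seq_len(n_quadrats)) {
    lam <- avail * mean_units_per_quadrat
    units <- stats::rpois(length(lam), lam)
    out[[q]] <- data.frame(site = site, period = period,
                           quadrat_id = sprintf("Q%02d", q),
                           plant_species = names(avail),
                           floral_units = units,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
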
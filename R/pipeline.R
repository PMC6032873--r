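#' Pipeline configuration
#'
#' Collects every path, threshold and simulation parameter the pipeline
#' uses. All thresholds are validated against their documented ranges. The
#' configuration round-trips losslessly through [write_config()] /
#' [read_config()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed governing every random stage.
#' @param reads_dir Optional directory with existing `reads_R1.fastq`,
#'   `reads_R2.fastq` and `metadata.tsv`; when given the simulate stage reads
#'   them instead of generating data.
#' @param reference_fasta Optional existing reference FASTA
#'   (`species|genus|family` headers); simulated when `NULL`.
#' @param allowlist Optional character vector of allowed taxon labels
#'   (filtering disabled when `NULL`).
#' @param sites,periods Site and period labels for simulation.
#' @param insects_per_cell Named vector: insects simulated per site for each
#'   period (default `c(early = 14, late = 31)`, an uneven seasonal capture
#'   pattern).
#' @param n_families,genera_per_family,species_per_genus,divergence Reference
#'   library simulation parameters, see [generate_reference_db()].
#' @param read_sim A [read_sim_config()].
#' @param min_length_exclusive Exclusive merged-length filter (default 450).
#' @param min_overlap,max_mismatch_fraction Pair-merging parameters.
#' @param trim_threshold,trim_window Quality-trimming parameters.
#' @param k K-mer size for the reference index.
#' @param top_n,genus_threshold,family_threshold Consensus parameters, see
#'   [assign_reads()].
#' @param consensus Consensus hit basis, see [assign_reads()].
#' @param classify_threshold Single-plant visitor threshold in percent.
#' @param presence_min_percent Presence threshold for interaction matrices.
#' @param pool_threshold Pooling threshold (percent, inclusive) for the
#'   "others" category in report tables.
#' @param fit_glmm Attempt the binomial mixed model in the classify stage.
#' @param stages Stages to run, in order, from
#'   `c("simulate", "assign", "networks", "classify", "report")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            reads_dir = NULL,
                            reference_fasta = NULL,
                            allowlist = NULL,
                            sites = c("S1", "S2"),
                            periods = c("early", "late"),
                            insects_per_cell = c(early = 14, late = 31),
                            n_families = 4, genera_per_family = 2,
                            species_per_genus = 2,
                            divergence = list(within_genus = 0.05,
                                              between_genus = 0.15),
                            read_sim = read_sim_config(),
                            min_length_exclusive = 450,
                            min_overlap = 20, max_mismatch_fraction = 0.1,
                            trim_threshold = 20, trim_window = 4,
                            k = 8, top_n = 20,
                            genus_threshold = 0.60, family_threshold = 0.90,
                            consensus = "top_score_ties",
                            classify_threshold = 90,
                            presence_min_percent = 0,
                            pool_threshold = 1.0,
                            fit_glmm = TRUE,
                            stages = c("simulate", "assign", "networks",
                                       "classify", "report")) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` to validate.
#' @export
validate_config <- function(config) {
  with(config, {
    stopifnot(is.numeric(seed), length(seed) == 1)
    if (min_length_exclusive < 0) stop("min_length_exclusive must be >= 0")
    if (genus_threshold < 0 || genus_threshold > 1)
      stop("genus_threshold must lie in [0, 1]")
    if (family_threshold < 0 || family_threshold > 1)
      stop("family_threshold must lie in [0, 1]")
    if (classify_threshold < 0 || classify_threshold > 100)
      stop("classify_threshold must lie in [0, 100]")
    if (presence_min_percent < 0 || presence_min_percent > 100)
      stop("presence_min_percent must lie in [0, 100]")
    if (top_n < 1) stop("top_n must be >= 1")
    bad <- setdiff(stages, c("simulate", "assign", "networks", "classify",
                             "report"))
    if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  })
  invisible(config)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$read_sim <- unclass(x$read_sim)
  x$insects_per_cell <- as.list(x$insects_per_cell)  # keep names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  rs <- do.call(read_sim_config, x$read_sim)
  x$read_sim <- NULL
  x$insects_per_cell <- unlist(x$insects_per_cell)
  cfg <- do.call(pipeline_config, c(x, list(read_sim = rs)))
  cfg
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Total flower unit score for a site and period
#'
#' Sums floral units over all quadrat records of the site x period cell. One
#' floral unit is one flower for most herbs, one inflorescence for Apiaceae,
#' one flowering spike for spike-forming taxa.
#'
#' @param survey Survey data.frame (`site`, `period`, `quadrat_id`,
#'   `plant_species`, `floral_units`).
#' @param site,period Cell selectors.
#' @return Integer total.
#' @export
flower_unit_score <- function(survey, site, period) {
  rows <- survey$site == site & survey$period == period
  as.integer(sum(survey$floral_units[rows]))
}

#' Pooled site x period pollen proportions with an "others" category
#'
#' Aggregates identified read counts per taxon over all insects of the cell,
#' converts to percent of the total, and pools every taxon at or below
#' `pool_threshold` percent into `"others"`. Proportions always sum to 100.
#'
#' @param profiles Tidy profile table from [profile_insects()].
#' @param site,period Cell selectors.
#' @param pool_threshold Inclusive pooling threshold in percent (default 1).
#' @return Data.frame `site`, `period`, `taxon`, `percent`, sorted
#'   descending with `"others"` last.
#' @export
pooled_proportions <- function(profiles, site, period, pool_threshold = 1.0) {
  p <- profiles[profiles$site == site & profiles$period == period, ,
                drop = FALSE]
  if (nrow(p) == 0) stop("no profiles for ", site, " / ", period)
  tot <- tapply(p$count, p$taxon, sum)
  pct <- 100 * tot / sum(tot)
  pool <- pct <= pool_threshold
  out <- data.frame(taxon = names(pct)[!pool], percent = unname(pct[!pool]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$taxon), , drop = FALSE]
  if (any(pool))
    out <- rbind(out, data.frame(taxon = "others",
                                 percent = sum(pct[pool]),
                                 stringsAsFactors = FALSE))
  data.frame(site = site, period = period, out, row.names = NULL,
             stringsAsFactors = FALSE)
}

log_line <- function(log, ...) c(log, paste0(...))

#' Run the full pollen metabarcoding pipeline
#'
#' Orchestrates simulation (or loading) of reads, quality trimming, pair
#' merging, length filtering, consensus taxonomic assignment, per-insect
#' profiling, network metrics, individual classification and report tables.
#' Every stage writes its intermediates as plain TSV/FASTA/FASTQ under
#' `config$out_dir`, so any stage can be inspected or re-run, and a summary
#' log records per-stage record counts. Output is deterministic given the
#' seed and inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-stage record `counts`, output `paths`
#'   and the main result tables.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  # fail before any stage runs if declared inputs are missing
  if (!is.null(config$reads_dir)) {
    need <- file.path(config$reads_dir,
                      c("reads_R1.fastq", "reads_R2.fastq", "metadata.tsv"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(config$reference_fasta) &&
      !file.exists(config$reference_fasta))
    stop("missing input file: ", config$reference_fasta)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)
  log <- character(0)
  counts <- list()
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  ## ---- simulate ----
  if ("simulate" %in% config$stages) stage("simulate", {
    if (is.null(config$reads_dir)) {
      set.seed(config$seed)
      db <- generate_reference_db(config$n_families,
                                  config$genera_per_family,
                                  config$species_per_genus,
                                  config$divergence,
                                  seq_length = config$read_sim$amplicon_length,
                                  seed = config$seed)
      write_reference_fasta(db, od("reference.fasta"))
      plant_ids <- db$taxa$species_id
      meta <- list(); props <- list(); survey <- list()
      cell_seed <- config$seed
      for (s in config$sites) for (p in config$periods) {
        cell_seed <- cell_seed + 1L
        set.seed(cell_seed)
        # site x period plant availability: lognormal weights, heavier and
        # more even flower resource late in the season
        avail <- setNames(rlnorm(length(plant_ids), 0,
                                 if (p == "early") 1.2 else 0.8), plant_ids)
        n <- unname(config$insects_per_cell[[p]])
        mix <- generate_insects(n, s, p, availability = avail,
                                seed = cell_seed)
        meta[[paste(s, p)]] <- mix$insects
        props[[paste(s, p)]] <- mix$proportions
        survey[[paste(s, p)]] <- generate_flower_survey(
          s, p, avail,
          mean_units_per_quadrat = if (p == "early") 4 else 8,
          seed = cell_seed)
      }
      metadata <- do.call(rbind, c(meta, make.row.names = FALSE))
      mixtures <- structure(list(
        insects = metadata,
        proportions = do.call(rbind, c(props, make.row.names = FALSE))),
        class = "synthetic_mixtures")
      reads <- generate_reads(mixtures, db, config$read_sim,
                              seed = config$seed + 1000L)
      write_fastq(reads$fwd, od("reads_R1.fastq"))
      write_fastq(reads$rev, od("reads_R2.fastq"))
      write_tsv(metadata, od("metadata.tsv"))
      write_tsv(mixtures$proportions, od("true_proportions.tsv"))
      write_tsv(reads$truth, od("truth.tsv"))
      write_tsv(do.call(rbind, c(survey, make.row.names = FALSE)),
                od("flower_survey.tsv"))
      counts$reads_in <- nrow(reads$fwd)
      log <- log_line(log, "simulate: ", nrow(metadata), " insects, ",
                       nrow(reads$fwd), " read pairs")
    } else {
      file.copy(file.path(config$reads_dir,
                          c("reads_R1.fastq", "reads_R2.fastq",
                            "metadata.tsv")),
                config$out_dir, overwrite = TRUE)
      if (!is.null(config$reference_fasta))
        file.copy(config$reference_fasta, od("reference.fasta"),
                  overwrite = TRUE)
      counts$reads_in <- nrow(read_fastq(od("reads_R1.fastq")))
      log <- log_line(log, "simulate: loaded existing reads (",
                       counts$reads_in, " pairs)")
    }
  })

  ## ---- assign ----
  if ("assign" %in% config$stages) stage("assign", {
    fwd <- read_fastq(od("reads_R1.fastq"))
    rev <- read_fastq(od("reads_R2.fastq"))
    counts$reads_in <- nrow(fwd)
    fwd <- quality_trim(fwd, config$trim_threshold, config$trim_window)
    rev <- quality_trim(rev, config$trim_threshold, config$trim_window)
    nonempty <- nchar(fwd$seq) > 0 & nchar(rev$seq) > 0
    mg <- merge_pairs(fwd[nonempty, ], rev[nonempty, ],
                      config$min_overlap, config$max_mismatch_fraction)
    if (any(!nonempty))
      mg$unmerged <- rbind(mg$unmerged,
                           data.frame(id = fwd$id[!nonempty],
                                      reason = "empty_after_trim",
                                      stringsAsFactors = FALSE))
    kept <- length_filter(mg$merged, config$min_length_exclusive)
    counts$merged <- nrow(mg$merged)
    counts$unmerged <- nrow(mg$unmerged)
    counts$passed_filter <- nrow(kept)
    counts$failed_filter <- nrow(mg$merged) - nrow(kept)
    write_fasta(kept, od("merged_filtered.fasta"))
    write_tsv(mg$unmerged, od("unmerged.tsv"))

    db <- build_reference_index(od("reference.fasta"), k = config$k)
    assignments <- assign_reads(kept, db,
                                top_n = config$top_n,
                                genus_threshold = config$genus_threshold,
                                family_threshold = config$family_threshold,
                                consensus = config$consensus)
    assignments <- filter_allowlist(assignments, config$allowlist, db)
    assignments$insect_id <- sub("_read\\d+$", "", assignments$read_id)
    counts$assigned <- sum(assignments$rank != "unknown")
    counts$unknown <- sum(assignments$rank == "unknown")
    write_tsv(assignments, od("assignments.tsv"))

    metadata <- read.table(od("metadata.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    profiles <- profile_insects(assignments, metadata)
    write_tsv(profiles, od("profiles.tsv"))
    write_tsv(attr(profiles, "excluded_insects"), od("excluded_insects.tsv"))
    results$profiles <- profiles
    per_insect <- tapply(assignments$rank != "unknown",
                         assignments$insect_id, sum)
    log <- log_line(log,
      "assign: ", counts$reads_in, " pairs in; ", counts$merged, " merged (",
      counts$unmerged, " unmerged); ", counts$passed_filter,
      " passed >", config$min_length_exclusive, " bp filter; ",
      counts$assigned, " identified, ", counts$unknown, " unknown; ",
      length(per_insect), " insects with reads, ",
      nrow(metadata) - sum(tapply(assignments$rank != "unknown",
                                  assignments$insect_id, sum) > 0),
      " of ", nrow(metadata), " excluded")
  })

  ## ---- networks ----
  if ("networks" %in% config$stages) stage("networks", {
    profiles <- results$profiles
    if (is.null(profiles))
      profiles <- read.table(od("profiles.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    results$profiles <- profiles
    cells <- unique(profiles[, c("site", "period")])
    for (i in seq_len(nrow(cells))) {
      mat <- build_interaction_matrix(profiles, cells$site[i],
                                      cells$period[i],
                                      config$presence_min_percent)
      write.table(mat, od(sprintf("matrix_%s_%s.tsv", cells$site[i],
                                  cells$period[i])),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
    metrics <- network_metrics_table(profiles, config$presence_min_percent)
    write_tsv(metrics, od("network_metrics.tsv"))
    results$metrics <- metrics
    log <- log_line(log, "networks: ", nrow(cells), " site x period cells")
  })

  ## ---- classify ----
  if ("classify" %in% config$stages) stage("classify", {
    profiles <- results$profiles
    if (is.null(profiles))
      profiles <- read.table(od("profiles.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    cl <- classify_individuals(profiles, config$classify_threshold)
    write_tsv(cl, od("classifications.tsv"))
    summ <- classification_summary(cl, c(config$classify_threshold, 60))
    write_tsv(summ$threshold_table, od("classification_thresholds.tsv"))
    write_tsv(summ$decile_table, od("classification_deciles.tsv"))
    results$classifications <- cl
    results$classification_summary <- summ
    if (isTRUE(config$fit_glmm)) {
      fit <- tryCatch(fit_binomial_glmm(cl), error = function(e) e)
      if (inherits(fit, "error")) {
        log <- log_line(log, "classify: glmm not fitted (",
                         conditionMessage(fit), ")")
      } else {
        write_tsv(fit$coefficients, od("glmm_coefficients.tsv"))
        write_tsv(data.frame(term = names(fit$varcomp),
                             variance = unname(fit$varcomp)),
                  od("glmm_varcomp.tsv"))
        results$glmm <- fit
      }
    }
    log <- log_line(log, "classify: ", nrow(cl), " insects classified (",
                     sum(cl$visitor_class == "single"), " single-plant)")
  })

  ## ---- report ----
  if ("report" %in% config$stages) stage("report", {
    profiles <- results$profiles
    if (is.null(profiles))
      profiles <- read.table(od("profiles.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    cells <- unique(profiles[, c("site", "period")])
    pooled <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      pooled_proportions(profiles, cells$site[i], cells$period[i],
                         config$pool_threshold)))
    write_tsv(pooled, od("pooled_proportions.tsv"))
    results$pooled <- pooled
    if (file.exists(od("flower_survey.tsv"))) {
      survey <- read.table(od("flower_survey.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
      sc <- unique(survey[, c("site", "period")])
      scores <- data.frame(
        site = sc$site, period = sc$period,
        flower_unit_score = vapply(seq_len(nrow(sc)), function(i)
          flower_unit_score(survey, sc$site[i], sc$period[i]), integer(1)),
        stringsAsFactors = FALSE)
      write_tsv(scores, od("flower_unit_scores.tsv"))
      results$flower_scores <- scores
    }
    log <- log_line(log, "report: pooled proportions for ", nrow(cells),
                     " cells")
  })

  writeLines(log, od("pipeline_log.txt"))
  invisible(list(counts = counts, log = log, out_dir = config$out_dir,
                 results = results))
}
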
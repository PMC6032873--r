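#' Alignment and bit-score scoring scheme
#'
#' Defaults follow the megablast +1/−2 convention: match +1, mismatch −2,
#' gap open −5, gap extend −2, with Karlin–Altschul constants lambda = 1.28
#' and K = 0.46 so that `bit = (lambda * S - log(K)) / log(2)`. The bit score
#' is strictly increasing in the raw score, so any strictly monotone
#' transform of raw scores yields identical taxonomic calls; the constants
#' affect reporting only.
#'
#' @param match,mismatch,gap_open,gap_extend Integer alignment scores
#'   (penalties negative).
#' @param lambda,K Karlin–Altschul constants for the bit-score transform.
#' @param band Half-width of the alignment band around the dominant shared
#'   k-mer diagonal (default 16).
#' @return List of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L, lambda = 1.28, K = 0.46,
                           band = 16L) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, band = as.integer(band)),
            class = "scoring_scheme")
}

bit_score <- function(raw, scoring) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

kmerize <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Build a k-mer-indexed reference database
#'
#' Accepts either a FASTA path whose headers follow the
#' `species|genus|family` convention, or a `taxonomy_truth` object from
#' [generate_reference_db()]. Every k-mer of every reference is indexed for
#' candidate prefiltering during scoring.
#'
#' @param ref FASTA path or `taxonomy_truth` object.
#' @param k K-mer size (default 8).
#' @return Object of class `pollen_ref_db`: list with `records` (data.frame
#'   `ref_id`, `species`, `genus`, `family`, `seq`), `index` (data.table
#'   `kmer`, `ref`, `pos`) and `k`.
#' @export
build_reference_index <- function(ref, k = 8) {
  if (inherits(ref, "taxonomy_truth")) {
    records <- data.frame(ref_id = ref$taxa$species_id,
                          species = ref$taxa$species_id,
                          genus = ref$taxa$genus_id,
                          family = ref$taxa$family_id,
                          seq = unname(ref$sequences[ref$taxa$species_id]),
                          stringsAsFactors = FALSE)
  } else {
    x <- Biostrings::readDNAStringSet(ref)
    parts <- strsplit(names(x), "|", fixed = TRUE)
    nfields <- lengths(parts)
    if (any(nfields != 3))
      stop("reference header does not parse to species|genus|family: ",
           names(x)[which(nfields != 3)[1]])
    records <- data.frame(ref_id = vapply(parts, `[`, "", 1),
                          species = vapply(parts, `[`, "", 1),
                          genus = vapply(parts, `[`, "", 2),
                          family = vapply(parts, `[`, "", 3),
                          seq = as.character(x), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(records$ref_id))
    stop("duplicate reference ids: ",
         records$ref_id[duplicated(records$ref_id)][1])
  if (any(records$species == "" | records$genus == "" | records$family == ""))
    stop("reference record with empty rank label")
  if (k > min(nchar(records$seq)))
    stop("k exceeds the shortest reference length")
  idx <- data.table::rbindlist(lapply(seq_len(nrow(records)), function(i) {
    km <- kmerize(records$seq[i], k)
    data.table::data.table(kmer = km, ref = i, pos = seq_along(km))
  }))
  data.table::setkey(idx, kmer)
  structure(list(records = records, index = idx, k = as.integer(k)),
            class = "pollen_ref_db")
}

# shared-k-mer candidate prefilter for a batch of reads: returns a data.table
# (read, ref, n_shared, center) where center is the dominant diagonal offset
kmer_candidates <- function(seqs, db, max_candidates) {
  k <- db$k
  rd <- data.table::rbindlist(lapply(seq_along(seqs), function(i) {
    km <- kmerize(seqs[i], k)
    if (!length(km)) return(NULL)
    data.table::data.table(read = i, kmer = km, rpos = seq_along(km))
  }))
  if (is.null(rd) || nrow(rd) == 0)
    return(data.table::data.table(read = integer(0), ref = integer(0),
                                  n_shared = integer(0), center = integer(0)))
  hits <- db$index[rd, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0)
    return(data.table::data.table(read = integer(0), ref = integer(0),
                                  n_shared = integer(0), center = integer(0)))
  hits[, offset := pos - rpos]
  cand <- hits[, {
    tb <- tabulate(offset - min(offset) + 1L)
    list(n_shared = .N, center = min(offset) + which.max(tb) - 1L)
  }, by = .(read, ref)]
  data.table::setorder(cand, read, -n_shared, ref)
  cand[, head(.SD, max_candidates), by = read]
}

#' Score a read against the reference database
#'
#' Candidates are prefiltered by shared-k-mer count, then scored by banded
#' local alignment (Smith–Waterman, affine gaps) anchored on the dominant
#' shared diagonal. Hits are sorted by bit score descending, ties broken by
#' reference id for determinism.
#'
#' @param read A single sequence string, or a one-row record data.frame.
#' @param db A `pollen_ref_db`.
#' @param scoring A [scoring_scheme()].
#' @param max_candidates Maximum candidates retained by the prefilter.
#' @return Hit table: data.frame `ref_id`, `species`, `genus`, `family`,
#'   `score`, `bit_score`, sorted best-first. Empty when the read shares no
#'   k-mer with any reference.
#' @export
score_hits <- function(read, db, scoring = scoring_scheme(),
                       max_candidates = 20) {
  if (is.data.frame(read)) read <- read$seq
  stopifnot(length(read) == 1, inherits(db, "pollen_ref_db"))
  if (nrow(db$records) == 0) stop("empty reference database")
  if (nchar(read) <= db$k) stop("read shorter than k-mer size")
  ht <- score_read_set(read, db, scoring, max_candidates)
  ht$read_id <- NULL
  ht
}

# bulk scorer: seqs is a character vector; returns one long sorted hit table
# with a read_id column (the integer position in seqs unless names given)
score_read_set <- function(seqs, db, scoring = scoring_scheme(),
                           max_candidates = 20) {
  ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_along(seqs))
  cand <- kmer_candidates(unname(seqs), db, max_candidates)
  if (nrow(cand) == 0)
    return(data.frame(read_id = character(0), ref_id = character(0),
                      species = character(0), genus = character(0),
                      family = character(0), score = integer(0),
                      bit_score = numeric(0), stringsAsFactors = FALSE))
  raw <- banded_local_scores(unname(seqs), db$records$seq,
                             cand$read, cand$ref, cand$center,
                             scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend,
                             scoring$band)
  out <- data.table::data.table(
    read_id = ids[cand$read],
    ref_id = db$records$ref_id[cand$ref],
    species = db$records$species[cand$ref],
    genus = db$records$genus[cand$ref],
    family = db$records$family[cand$ref],
    score = raw)
  out <- out[score > 0]
  out[, bit_score := bit_score(score, scoring)]
  data.table::setorder(out, read_id, -bit_score, ref_id)
  as.data.frame(out)
}

#' Retain the hits with the n highest bit scores
#'
#' All hits tied with the n-th best bit score are retained, so the result can
#' exceed `n` rows under ties.
#'
#' @param hits Hit table sorted best-first (as from [score_hits()]).
#' @param n Number of top scores to keep (default 20).
#' @return Filtered hit table.
#' @export
top_hits <- function(hits, n = 20) {
  if (nrow(hits) <= n) return(hits)
  cutoff <- sort(hits$bit_score, decreasing = TRUE)[n]
  hits[hits$bit_score >= cutoff, , drop = FALSE]
}

#' Consensus taxonomic call from a table of retained hits
#'
#' The rules, applied to the hit records in the given table: (1) if every hit
#' is the same species, assign that species; (2) else if at least
#' `genus_threshold` of hits share one genus, assign that genus; (3) else the
#' read is "various": assign the family (or tribe) shared by at least
#' `family_threshold` of hits if one exists, otherwise "unknown". Thresholds
#' are inclusive. The call is scale-free: duplicating every hit leaves it
#' unchanged.
#'
#' @param top Hit table (typically the hits sharing the maximum bit score,
#'   see [assign_reads()]).
#' @param genus_threshold Minimum hit fraction for a genus call (default
#'   0.60).
#' @param family_threshold Minimum hit fraction for a family/tribe call
#'   (default 0.90).
#' @return List of class `taxon_assignment`: `taxon`, `rank` (one of
#'   `"species"`, `"genus"`, `"family_tribe"`, `"unknown"`) and
#'   `supporting_hit_fraction`.
#' @export
assign_taxon <- function(top, genus_threshold = 0.60,
                         family_threshold = 0.90) {
  n <- nrow(top)
  if (is.null(n) || n == 0)
    return(structure(list(taxon = "unknown", rank = "unknown",
                          supporting_hit_fraction = 0),
                     class = "taxon_assignment"))
  sp <- unique(top$species)
  if (length(sp) == 1)
    return(structure(list(taxon = sp, rank = "species",
                          supporting_hit_fraction = 1.0),
                     class = "taxon_assignment"))
  gtab <- sort(table(top$genus), decreasing = TRUE)
  if (gtab[1] / n >= genus_threshold)
    return(structure(list(taxon = names(gtab)[1], rank = "genus",
                          supporting_hit_fraction = unname(gtab[1]) / n),
                     class = "taxon_assignment"))
  ftab <- sort(table(top$family), decreasing = TRUE)
  if (ftab[1] / n >= family_threshold)
    return(structure(list(taxon = names(ftab)[1], rank = "family_tribe",
                          supporting_hit_fraction = unname(ftab[1]) / n),
                     class = "taxon_assignment"))
  structure(list(taxon = "unknown", rank = "unknown",
                 supporting_hit_fraction = unname(ftab[1]) / n),
            class = "taxon_assignment")
}

#' Assign a set of merged reads to taxa
#'
#' Bulk pipeline operation: scores every read against the reference
#' database, retains the top `top_n` hits per read, restricts the consensus
#' to the hits sharing the maximum bit score (`consensus = "top_score_ties"`,
#' the default, matching how "top maximum bit scores" behave when a species
#' is represented by many accessions) or uses all retained hits
#' (`"all_retained"`), and applies [assign_taxon()] per read. Reads with no
#' hits are "unknown".
#'
#' @param reads Record data.frame (`id`, `seq`) of merged reads, or a named
#'   character vector of sequences.
#' @param db A `pollen_ref_db`.
#' @param scoring A [scoring_scheme()].
#' @param top_n Hits retained per read before consensus (default 20).
#' @param genus_threshold,family_threshold Consensus thresholds, see
#'   [assign_taxon()].
#' @param consensus Which retained hits enter the consensus.
#' @param max_candidates Prefilter cap per read (default 20).
#' @param chunk_size Reads scored per batch, bounding the memory of the
#'   k-mer join (default 2000).
#' @return Data.frame `read_id`, `taxon`, `rank`, `support`.
#' @export
assign_reads <- function(reads, db, scoring = scoring_scheme(), top_n = 20,
                         genus_threshold = 0.60, family_threshold = 0.90,
                         consensus = c("top_score_ties", "all_retained"),
                         max_candidates = 20, chunk_size = 2000) {
  consensus <- match.arg(consensus)
  if (is.data.frame(reads)) {
    seqs <- setNames(reads$seq, reads$id)
  } else seqs <- reads
  if (length(seqs) == 0)
    return(data.frame(read_id = character(0), taxon = character(0),
                      rank = character(0), support = numeric(0),
                      stringsAsFactors = FALSE))
  chunks <- split(seq_along(seqs), ceiling(seq_along(seqs) / chunk_size))
  res <- lapply(chunks, function(ix) {
    ht <- data.table::as.data.table(
      score_read_set(seqs[ix], db, scoring, max_candidates))
    if (nrow(ht) == 0) return(NULL)
    # per-read top-n (ties at rank n kept), then optional tie-at-max restriction
    ht[, keep_hit := {
      if (.N <= top_n) rep(TRUE, .N)
      else bit_score >= sort(bit_score, decreasing = TRUE)[top_n]
    }, by = read_id]
    ht <- ht[keep_hit == TRUE]
    if (consensus == "top_score_ties")
      ht <- ht[, .SD[score == max(score)], by = read_id]
    ht[, {
      a <- assign_taxon(.SD, genus_threshold, family_threshold)
      list(taxon = a$taxon, rank = a$rank, support = a$supporting_hit_fraction)
    }, by = read_id]
  })
  res <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  out <- data.frame(read_id = names(seqs), stringsAsFactors = FALSE)
  out <- merge(out, as.data.frame(res), by = "read_id", all.x = TRUE,
               sort = FALSE)
  out$taxon[is.na(out$taxon)] <- "unknown"
  out$rank[is.na(out$rank)] <- "unknown"
  out$support[is.na(out$support)] <- 0
  # merge() may reorder; restore input order
  out[match(names(seqs), out$read_id), , drop = FALSE]
}

#' Filter assignments against a taxon allow-list
#'
#' Assignments whose label, or an ancestor of it, appears in the allow-list
#' are retained; others are removed. The allow-list may mix ranks: a
#' genus-level entry admits species-level calls within that genus, a family
#' entry admits genus and species calls within the family. Unknown-rank
#' assignments are always retained (they are excluded later at the profile
#' stage). With `allowlist = NULL` filtering is disabled and the input is
#' returned unchanged.
#'
#' @param assignments Data.frame `read_id`, `taxon`, `rank`, `support`.
#' @param allowlist Character vector of allowed taxon labels at any rank, or
#'   `NULL` to disable filtering.
#' @param db A `pollen_ref_db` supplying ancestor relationships.
#' @return Filtered assignments.
#' @export
filter_allowlist <- function(assignments, allowlist, db = NULL) {
  if (is.null(allowlist)) return(assignments)
  if (is.null(db)) stop("db is required to resolve ancestor labels")
  rec <- db$records
  sp2gen <- setNames(rec$genus, rec$species)
  sp2fam <- setNames(rec$family, rec$species)
  gen2fam <- setNames(rec$family, rec$genus)
  ok <- vapply(seq_len(nrow(assignments)), function(i) {
    tx <- assignments$taxon[i]
    rk <- assignments$rank[i]
    if (rk == "unknown") return(TRUE)
    anc <- switch(rk,
                  species = c(tx, unname(sp2gen[tx]), unname(sp2fam[tx])),
                  genus = c(tx, unname(gen2fam[tx])),
                  family_tribe = tx)
    any(anc %in% allowlist, na.rm = TRUE)
  }, logical(1))
  assignments[ok, , drop = FALSE]
}

#' Per-insect pollen profile from read assignments
#'
#' Groups identified reads (rank other than "unknown") by taxon and converts
#' counts to percentages of identified reads, controlling for differences in
#' per-sample amplification. Insects with no identified reads are flagged
#' excluded.
#'
#' @param assignments Assignments for a single insect.
#' @param metadata One-row data.frame with `insect_id`, `insect_species`,
#'   `sex`, `site`, `period`.
#' @return List of class `pollen_profile`: `insect_id`, `insect_species`,
#'   `sex`, `site`, `period`, `counts` (named integer), `percents` (named
#'   numeric summing to 100 when any identified reads exist), `excluded`.
#' @export
profile_insect <- function(assignments, metadata) {
  req <- c("insect_id", "insect_species", "sex", "site", "period")
  if (!all(req %in% names(metadata)))
    stop("metadata missing required fields: ",
         paste(setdiff(req, names(metadata)), collapse = ", "))
  idf <- assignments[assignments$rank != "unknown", , drop = FALSE]
  if (nrow(idf) == 0) {
    return(structure(list(insect_id = metadata$insect_id,
                          insect_species = metadata$insect_species,
                          sex = metadata$sex, site = metadata$site,
                          period = metadata$period,
                          counts = integer(0), percents = numeric(0),
                          excluded = TRUE),
                     class = "pollen_profile"))
  }
  counts <- sort(table(idf$taxon), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  percents <- 100 * counts / sum(counts)
  structure(list(insect_id = metadata$insect_id,
                 insect_species = metadata$insect_species,
                 sex = metadata$sex, site = metadata$site,
                 period = metadata$period,
                 counts = counts, percents = percents, excluded = FALSE),
            class = "pollen_profile")
}

#' Tidy pollen-profile table for a set of insects
#'
#' Applies [profile_insect()] per insect and binds the results into a tidy
#' table with one row per insect x taxon. Insects present in `metadata` but
#' with no identified reads are recorded in the `excluded_insects` attribute
#' rather than the table.
#'
#' @param assignments Data.frame with `read_id`, `insect_id`, `taxon`,
#'   `rank`, `support`.
#' @param metadata Data.frame with one row per insect (`insect_id`,
#'   `insect_species`, `sex`, `site`, `period`).
#' @return Data.frame `insect_id`, `insect_species`, `sex`, `site`, `period`,
#'   `taxon`, `count`, `percent`, with attribute `excluded_insects`.
#' @export
profile_insects <- function(assignments, metadata) {
  stopifnot("insect_id" %in% names(assignments))
  rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(metadata))) {
    md <- metadata[i, , drop = FALSE]
    a <- assignments[assignments$insect_id == md$insect_id, , drop = FALSE]
    p <- profile_insect(a, md)
    if (p$excluded) {
      excluded[[length(excluded) + 1L]] <- md
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      insect_id = p$insect_id, insect_species = p$insect_species,
      sex = p$sex, site = p$site, period = p$period,
      taxon = names(p$counts), count = unname(p$counts),
      percent = unname(p$percents), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(insect_id = character(0), insect_species = character(0),
               sex = character(0), site = character(0), period = character(0),
               taxon = character(0), count = integer(0), percent = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "excluded_insects") <-
    if (length(excluded)) do.call(rbind, c(excluded, make.row.names = FALSE)) else
      metadata[0, , drop = FALSE]
  out
}
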
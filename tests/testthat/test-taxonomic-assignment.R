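make_db <- function(seed = 1, nf = 2, gpf = 2, spg = 2, w = 0.03, b = 0.12) {
  generate_reference_db(nf, gpf, spg,
                        divergence = list(within_genus = w, between_genus = b),
                        seed = seed)
}

test_that("the k-mer index retrieves each reference by any of its k-mers", {
  db <- build_reference_index(make_db(), k = 8)
  for (i in sample(nrow(db$records), 3)) {
    km <- substring(db$records$seq[i], 1:5, 8:12)  # a few leading 8-mers
    hits <- db$index[db$index$kmer %in% km, ]
    expect_true(i %in% hits$ref)
  }
})

test_that("reference headers must parse to three ranks", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">spA|genA", "ACGTACGTACGT"), f)  # family missing
  expect_error(build_reference_index(f, k = 4), "species\\|genus\\|family")
})

test_that("duplicate reference ids and oversized k are rejected", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">spA|genA|famA", "ACGTACGTACGT",
               ">spA|genA|famA", "ACGTACGTACGT"), f)
  expect_error(build_reference_index(f, k = 4), "duplicate")
  writeLines(c(">spA|genA|famA", "ACGTACGT"), f)
  expect_error(build_reference_index(f, k = 20), "shortest reference")
})

test_that("raw and bit scores match the closed-form values", {
  db0 <- make_db()
  db <- build_reference_index(db0, k = 8)
  sp <- db0$taxa$species_id[1]
  ref_seq <- db0$sequences[[sp]]
  h <- score_hits(ref_seq, db)
  expect_equal(h$score[1], 500)
  expect_equal(h$ref_id[1], sp)
  # bit score from the stated constants, computed independently
  expect_equal(h$bit_score[1], (1.28 * 500 - log(0.46)) / log(2),
               tolerance = 1e-12)
  # one mismatch: one match lost (-1) and one mismatch penalty (-2)
  mut <- ref_seq
  b <- substr(mut, 250, 250)
  substr(mut, 250, 250) <- setdiff(c("A", "C", "G", "T"), b)[1]
  h2 <- score_hits(mut, db)
  expect_equal(h2$score[h2$ref_id == sp], 497)
})

test_that("a read sharing no k-mer with the database yields no hits", {
  db <- build_reference_index(make_db(), k = 8)
  # homopolymer shares no 8-mer with random-ish references
  h <- score_hits(strrep("A", 100), db)
  expect_equal(nrow(h), 0)
})

test_that("bit scores increase strictly with raw score", {
  s <- scoring_scheme()
  raw <- c(10, 50, 100, 400, 500)
  bits <- (s$lambda * raw - log(s$K)) / log(2)
  expect_true(all(diff(bits) > 0))
})

test_that("top_hits keeps ties at the cutoff and short tables whole", {
  ht25 <- hit_table(paste0("s", 1:25), paste0("g", 1:25), paste0("f", 1:25),
                    score = 100)
  expect_equal(nrow(top_hits(ht25, 20)), 25)   # all tied, all kept
  ht5 <- hit_table(paste0("s", 1:5), paste0("g", 1:5), paste0("f", 1:5))
  expect_equal(nrow(top_hits(ht5, 20)), 5)
  ht <- hit_table(paste0("s", 1:30), paste0("g", 1:30), paste0("f", 1:30),
                  score = seq(100, by = -1, length.out = 30))
  expect_equal(nrow(top_hits(ht, 20)), 20)
})

test_that("consensus rules follow the species/genus/family precedence", {
  # all hits one species
  a <- assign_taxon(hit_table(rep("spA", 20), rep("gA", 20), rep("fA", 20)))
  expect_equal(a$taxon, "spA")
  expect_equal(a$rank, "species")
  expect_equal(a$supporting_hit_fraction, 1.0)
  # exactly 60% of hits one genus: inclusive boundary
  a <- assign_taxon(hit_table(paste0("sp", 1:20),
                              c(rep("gG", 12), paste0("g", 1:8)),
                              rep("fA", 20)))
  expect_equal(a$rank, "genus")
  expect_equal(a$taxon, "gG")
  expect_equal(a$supporting_hit_fraction, 0.60)
  # 55% genus consensus fails, 100% family consensus resolves "various"
  a <- assign_taxon(hit_table(paste0("sp", 1:20),
                              c(rep("gG", 11), paste0("g", 1:9)),
                              rep("fF", 20)))
  expect_equal(a$rank, "family_tribe")
  expect_equal(a$taxon, "fF")
  # nothing agrees: unknown
  a <- assign_taxon(hit_table(paste0("sp", 1:10), paste0("g", 1:10),
                              paste0("f", 1:10)))
  expect_equal(a$rank, "unknown")
  # empty table
  a <- assign_taxon(hit_table(character(0), character(0), character(0)))
  expect_equal(a$rank, "unknown")
  expect_equal(a$supporting_hit_fraction, 0)
})

test_that("the consensus is scale-free: duplicating every hit changes nothing", {
  ht <- hit_table(paste0("sp", 1:20), c(rep("gG", 12), paste0("g", 1:8)),
                  rep("fA", 20))
  a1 <- assign_taxon(ht)
  a2 <- assign_taxon(rbind(ht, ht))
  expect_equal(a1$taxon, a2$taxon)
  expect_equal(a1$rank, a2$rank)
  expect_equal(a1$supporting_hit_fraction, a2$supporting_hit_fraction)
})

test_that("allow-list filtering removes unlisted taxa but honours ancestors", {
  db0 <- make_db()
  db <- build_reference_index(db0, k = 8)
  sp <- db0$taxa$species_id[1:3]
  asg <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                    taxon = c(sp[1], sp[2], db0$taxa$genus_id[3], "unknown"),
                    rank = c("species", "species", "genus", "unknown"),
                    support = c(1, 1, 0.8, 0), stringsAsFactors = FALSE)
  # sp[1] listed directly; sp[2] admitted via its genus; genus call of read 3
  # admitted via its family
  allow <- c(sp[1], db0$taxa$genus_id[2], db0$taxa$family_id[3])
  kept <- filter_allowlist(asg, allow, db)
  expect_setequal(kept$read_id, c("r1", "r2", "r3", "r4"))
  # nothing listed: only the unknown (excluded later) survives
  kept2 <- filter_allowlist(asg, "somewhere_else", db)
  expect_equal(kept2$read_id, "r4")
  # NULL disables filtering entirely
  expect_identical(filter_allowlist(asg, NULL), asg)
})

test_that("profiles convert counts to percentages and flag empty insects", {
  md <- data.frame(insect_id = "i1", insect_species = "E_tenax", sex = "F",
                   site = "S1", period = "early", stringsAsFactors = FALSE)
  asg <- data.frame(read_id = sprintf("r%03d", 1:1000),
                    taxon = c(rep("X", 900), rep("Y", 100)),
                    rank = "species", support = 1, stringsAsFactors = FALSE)
  p <- profile_insect(asg, md)
  expect_equal(unname(p$percents["X"]), 90)
  expect_equal(unname(p$percents["Y"]), 10)
  expect_equal(sum(p$percents), 100, tolerance = 1e-6)
  # single taxon
  p1 <- profile_insect(asg[asg$taxon == "X", ], md)
  expect_equal(unname(p1$percents["X"]), 100)
  # only unknowns: excluded
  unk <- data.frame(read_id = "r1", taxon = "unknown", rank = "unknown",
                    support = 0, stringsAsFactors = FALSE)
  expect_true(profile_insect(unk, md)$excluded)
  expect_error(profile_insect(asg, md[, -2]), "metadata missing")
})

test_that("error-free reads are assigned perfectly at modest divergence", {
  db0 <- make_db(seed = 5, w = 0.05, b = 0.15)
  db <- build_reference_index(db0, k = 8)
  avail <- setNames(rep(1, nrow(db0$taxa)), db0$taxa$species_id)
  mix <- generate_insects(5, "S1", "early", availability = avail, seed = 5)
  rd <- generate_reads(mix, db0, read_sim_config(depth = 30, error_rate = 0),
                       seed = 5)
  mg <- merge_pairs(rd$fwd, rd$rev)
  kept <- length_filter(mg$merged, 450)
  asg <- assign_reads(kept, db)
  truth <- rd$truth$species_id[match(asg$read_id, rd$truth$read_id)]
  expect_true(all(asg$rank == "species"))
  expect_true(all(asg$taxon == truth))
})

test_that("reads from identical reference twins always resolve at genus rank", {
  db0 <- generate_reference_db(2, 2, 2,
                               divergence = list(within_genus = 0,
                                                 between_genus = 0.12),
                               seed = 9)
  db <- build_reference_index(db0, k = 8)
  twin <- db0$taxa$species_id[1:2]   # same genus, identical sequences
  expect_identical(db0$sequences[[twin[1]]], db0$sequences[[twin[2]]])
  reads <- setNames(substr(db0$sequences[[twin[1]]], 1, 500), "r1")
  asg <- assign_reads(reads, db)
  expect_equal(asg$rank, "genus")
  expect_equal(asg$taxon, db0$taxa$genus_id[1])
})
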
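test_that("zero within-genus divergence forces identical species sequences", {
  db <- generate_reference_db(1, 1, 2,
                              divergence = list(within_genus = 0,
                                                between_genus = 0),
                              seed = 7)
  expect_identical(db$sequences[[1]], db$sequences[[2]])
})

test_that("reference generation is seed-deterministic down to the FASTA bytes", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  db1 <- generate_reference_db(1, 1, 2,
                               divergence = list(within_genus = 0.02,
                                                 between_genus = 0.02),
                               seed = 7)
  db2 <- generate_reference_db(1, 1, 2,
                               divergence = list(within_genus = 0.02,
                                                 between_genus = 0.02),
                               seed = 7)
  write_reference_fasta(db1, f1)
  write_reference_fasta(db2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("within-genus pairs are closer than between-genus pairs", {
  db <- generate_reference_db(2, 2, 2,
                              divergence = list(within_genus = 0.02,
                                                between_genus = 0.08),
                              seed = 1)
  tx <- db$taxa
  within <- c(); between <- c()
  for (i in 1:(nrow(tx) - 1)) for (j in (i + 1):nrow(tx)) {
    h <- hamming_frac(db$sequences[[tx$species_id[i]]],
                      db$sequences[[tx$species_id[j]]])
    if (tx$genus_id[i] == tx$genus_id[j]) within <- c(within, h)
    else between <- c(between, h)
  }
  expect_lt(mean(within), mean(between))
})

test_that("divergence ordering and range are validated", {
  expect_error(generate_reference_db(1, 1, 2,
                                     divergence = list(within_genus = 0.1,
                                                       between_genus = 0.05)),
               "within-genus")
  expect_error(generate_reference_db(1, 1, 2,
                                     divergence = list(within_genus = -0.1,
                                                       between_genus = 0.5)),
               "divergence")
})

test_that("specialist probability 1 yields only near-pure mixtures", {
  avail <- c(p1 = 1, p2 = 1, p3 = 1, p4 = 1)
  mix <- generate_insects(10, "S1", "early", availability = avail,
                          specialist_prob = 1, seed = 3)
  mx <- tapply(mix$proportions$proportion, mix$proportions$insect_id, max)
  expect_true(all(mx >= 0.9))
  expect_true(all(mix$insects$specialist))
})

test_that("pure generalists over four equal taxa rarely look single-plant", {
  avail <- c(p1 = 1, p2 = 1, p3 = 1, p4 = 1)
  mix <- generate_insects(300, "S1", "early", availability = avail,
                          specialist_prob = 0, seed = 11)
  mx <- tapply(mix$proportions$proportion, mix$proportions$insect_id, max)
  # Monte-Carlo: E(max of a symmetric Dirichlet over 2-6 taxa) is well below
  # the 0.9 dominance threshold
  expect_lt(mean(mx), 0.9)
})

test_that("taxa with zero availability never occur in mixtures", {
  avail <- c(p1 = 1, p2 = 0, p3 = 2)
  mix <- generate_insects(50, "S1", "late", availability = avail, seed = 5)
  expect_false("p2" %in% mix$proportions$species_id)
})

test_that("mixture proportions are nonnegative and sum to one per insect", {
  avail <- setNames(runif(8) + 0.1, paste0("p", 1:8))
  mix <- generate_insects(40, "S2", "late", availability = avail, seed = 9)
  sums <- tapply(mix$proportions$proportion, mix$proportions$insect_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(mix$proportions$proportion >= 0))
})

test_that("empty availability is rejected", {
  expect_error(generate_insects(5, "S1", "early",
                                availability = c(a = 0, b = 0)),
               "availability")
})

test_that("error-free single-taxon reads reproduce the amplicon exactly", {
  db <- generate_reference_db(1, 1, 1, divergence = list(within_genus = 0,
                                                         between_genus = 0),
                              seed = 2)
  sp <- db$taxa$species_id[1]
  mix <- structure(list(
    insects = data.frame(insect_id = "i1", insect_species = "E_tenax",
                         sex = "F", site = "S1", period = "early",
                         specialist = TRUE, stringsAsFactors = FALSE),
    proportions = data.frame(insect_id = "i1", species_id = sp,
                             proportion = 1, stringsAsFactors = FALSE)),
    class = "synthetic_mixtures")
  cfg <- read_sim_config(depth = 100, error_rate = 0)
  rd <- generate_reads(mix, db, cfg, seed = 4)
  amp <- substr(db$sequences[[sp]], 1, 500)
  expect_equal(nrow(rd$fwd), 100)
  expect_true(all(rd$fwd$seq == substr(amp, 1, 300)))
  expect_true(all(rd$rev$seq == rc(substr(amp, 201, 500))))
  expect_true(all(rd$truth$species_id == sp))
})

test_that("zero depth yields empty FASTQ and truth table", {
  db <- generate_reference_db(1, 1, 1, seed = 2)
  sp <- db$taxa$species_id[1]
  mix <- structure(list(
    insects = data.frame(insect_id = "i1", insect_species = "E_tenax",
                         sex = "F", site = "S1", period = "early",
                         specialist = TRUE, stringsAsFactors = FALSE),
    proportions = data.frame(insect_id = "i1", species_id = sp,
                             proportion = 1, stringsAsFactors = FALSE)),
    class = "synthetic_mixtures")
  rd <- generate_reads(mix, db, read_sim_config(depth = 0), seed = 4)
  expect_equal(nrow(rd$fwd), 0)
  expect_equal(nrow(rd$truth), 0)
})

test_that("source sampling follows mixture proportions within binomial error", {
  db <- generate_reference_db(1, 1, 2, divergence = list(within_genus = 0.05,
                                                         between_genus = 0.05),
                              seed = 2)
  sp <- db$taxa$species_id
  mix <- structure(list(
    insects = data.frame(insect_id = "i1", insect_species = "E_tenax",
                         sex = "F", site = "S1", period = "early",
                         specialist = TRUE, stringsAsFactors = FALSE),
    proportions = data.frame(insect_id = "i1", species_id = sp,
                             proportion = c(0.9, 0.1),
                             stringsAsFactors = FALSE)),
    class = "synthetic_mixtures")
  rd <- generate_reads(mix, db, read_sim_config(depth = 1000), seed = 8)
  nA <- sum(rd$truth$species_id == sp[1])
  sd3 <- 3 * sqrt(1000 * 0.9 * 0.1)
  expect_lt(abs(nA - 900), sd3)
})

test_that("every generated read id appears exactly once in the truth table", {
  db <- generate_reference_db(2, 1, 2, seed = 6)
  avail <- setNames(rep(1, 4), db$taxa$species_id)
  mix <- generate_insects(6, "S1", "early", availability = avail, seed = 6)
  rd <- generate_reads(mix, db, read_sim_config(depth = 20), seed = 6)
  expect_identical(sort(rd$fwd$id), sort(rd$truth$read_id))
  expect_false(anyDuplicated(rd$truth$read_id) > 0)
})

test_that("read simulation rejects impossible geometry and error rates", {
  expect_error(read_sim_config(read_length = 600, amplicon_length = 500),
               "read_length")
  expect_error(read_sim_config(error_rate = 0.3), "error_rate")
  expect_error(read_sim_config(depth = -1), "depth")
})
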
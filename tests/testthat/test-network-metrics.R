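test_that("two-dimensional Shannon entropy matches hand values", {
  expect_equal(shannon_entropy(matrix(c(1, 1, 1, 1), 2)), log(4))
  expect_equal(shannon_entropy(matrix(c(4, 0, 0, 0), 2)), 0)
  expect_equal(shannon_entropy(matrix(c(2, 0, 0, 2), 2)), log(2))
  expect_error(shannon_entropy(matrix(0, 2, 2)), "m = 0")
})

test_that("the enumeration oracle reproduces exhaustive extremes", {
  e <- enumerate_entropy_extremes(c(2, 2), c(2, 2))
  expect_equal(unname(e), c(log(2), log(4)))
  e <- enumerate_entropy_extremes(c(1, 1), c(1, 1))
  expect_equal(unname(e), c(log(2), log(2)))
  e <- enumerate_entropy_extremes(4, 4)
  expect_equal(unname(e), c(0, 0))
  expect_error(enumerate_entropy_extremes(c(10, 10), c(10, 10)), "cap")
})

test_that("heuristic entropy bounds match the spec'd examples", {
  b <- h2_bounds(c(2, 2), c(2, 2))
  expect_equal(unname(b), c(log(2), log(4)))
  b <- h2_bounds(5, 5)            # single forced cell
  expect_equal(unname(b), c(0, 0))
  # all-ones 4x4 marginals, checked against the exhaustive oracle (m = 4)
  e <- enumerate_entropy_extremes(rep(1, 4), rep(1, 4))
  b <- h2_bounds(rep(1, 4), rep(1, 4))
  expect_equal(b[["H2min"]], e[["min"]], tolerance = 1e-9)
  expect_gte(b[["H2max"]] + 1e-9, e[["max"]])
})

test_that("H2' hits both endpoints on the canonical matrices", {
  h <- h2_prime(matrix(c(2, 0, 0, 2), 2))
  expect_equal(h$H2prime, 1)
  h <- h2_prime(matrix(c(1, 1, 1, 1), 2))
  expect_equal(h$H2prime, 0)
  h <- h2_prime(matrix(5, 1, 1))
  expect_equal(h$H2prime, 0)     # degenerate: H2max = H2min
})

test_that("perfect diagonals give H2' = 1 and independence-like rows give 0", {
  for (k in 2:5) {
    expect_equal(h2_prime(diag(k) * 3)$H2prime, 1)
  }
  # rows proportional to column totals = independence = maximal evenness
  m <- outer(c(2, 4), c(3, 1, 4))
  expect_equal(h2_prime(m)$H2prime, 0)
})

test_that("H2 and H2' are invariant under row and column permutation", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(rpois(12, 2), 3, 4)
    if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    mp <- m[sample(3), sample(4)]
    expect_equal(shannon_entropy(m), shannon_entropy(mp))
    expect_equal(h2_prime(m)$H2prime, h2_prime(mp)$H2prime, tolerance = 1e-9)
  }
})

test_that("d and d' match closed-form values on the canonical matrices", {
  m <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("A", "B"), c("x", "y")))
  d <- d_prime(m)
  expect_equal(d$d, c(0, 0))
  expect_equal(d$dprime, c(0, 0))
  m <- matrix(c(2, 0, 0, 2), 2, dimnames = list(c("A", "B"), c("x", "y")))
  d <- d_prime(m)
  expect_equal(d$d, c(log(2), log(2)))
  expect_equal(d$dmax, c(log(2), log(2)))
  expect_equal(d$dmin, c(0, 0))
  expect_equal(d$dprime, c(1, 1))
})

test_that("d' stays in [0,1] and zero-capture species are omitted", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(rpois(12, 1.5), 3, 4,
                dimnames = list(paste0("sp", 1:3), paste0("t", 1:4)))
    if (sum(m) == 0 || all(colSums(m) == 0)) next
    keep <- colSums(m) > 0
    d <- d_prime(m)
    expect_true(all(d$dprime >= 0 & d$dprime <= 1))
    expect_setequal(d$species, rownames(m)[rowSums(m) > 0])
  }
})

test_that("full concentration on the rarest partner maximises d", {
  # background matrix fixes the other species' interactions; enumerate every
  # integer allocation of the focal row and check that placing everything on
  # the partner with the rarest background use attains the maximal divergence
  base <- matrix(c(0, 0, 0, 8, 4, 2), 2, 3, byrow = TRUE,
                 dimnames = list(c("focal", "bg"), c("t1", "t2", "t3")))
  A <- 4
  d_of <- function(alloc) {
    m <- base
    m["focal", ] <- alloc
    d_prime(m)[d_prime(m)$species == "focal", "d"]
  }
  all_d <- vapply(compositions_of(A, 3), d_of, numeric(1))
  d_rarest <- d_of(c(0, 0, A))   # t3 has the rarest background use
  expect_equal(d_rarest, max(all_d), tolerance = 1e-12)
})

test_that("the integer minimum-divergence allocation matches enumeration", {
  set.seed(41)
  for (rep in 1:8) {
    q <- runif(3) + 0.05
    q <- q / sum(q)
    A <- sample(2:6, 1)
    kl <- function(n) {
      p <- n / A
      sum(ifelse(p > 0, p * log(p / q), 0))
    }
    brute <- min(vapply(compositions_of(A, 3), kl, numeric(1)))
    got <- pollenNet:::min_kl_allocation(A, q)
    expect_equal(kl(got), brute, tolerance = 1e-9)
  }
})

test_that("interaction matrices count individuals on a presence basis", {
  profs <- rbind(
    profile_rows("i1", c("X", "Y"), c(99, 1), insect_species = "A"),
    profile_rows("i2", c("X"), 50, insect_species = "A"),
    profile_rows("i3", c("Y"), 10, insect_species = "B"))
  m <- build_interaction_matrix(profs, "S1", "early")
  expect_equal(m["A", "X"], 2L)
  expect_equal(m["A", "Y"], 1L)   # the 1% taxon still counts as presence
  expect_equal(m["B", "Y"], 1L)
  # a presence threshold drops the trace taxon
  m5 <- build_interaction_matrix(profs, "S1", "early",
                                 presence_min_percent = 5)
  expect_equal(m5["A", "Y"], 0L)
  # empty cell
  m0 <- build_interaction_matrix(profs, "S9", "late")
  expect_equal(sum(m0), 0)
})

test_that("heuristic bounds agree with the oracle across small marginals", {
  # canonical (sorted) marginal pairs with m <= 6 up to 3x3; the full m <= 10
  # sweep runs in the acceptance suite
  parts <- list()
  for (m in 2:6) {
    ps <- unique(lapply(compositions_of(m, 3), function(x)
      sort(x[x > 0], decreasing = TRUE)))
    ps <- ps[lengths(ps) > 0]
    for (r in ps) for (co in ps) parts[[length(parts) + 1L]] <- list(r, co)
  }
  for (pr in parts) {
    ex <- enumerate_entropy_extremes(pr[[1]], pr[[2]])
    b <- h2_bounds(pr[[1]], pr[[2]])
    expect_equal(b[["H2min"]], ex[["min"]], tolerance = 1e-9)
    expect_gte(b[["H2max"]] + 1e-9, ex[["max"]])
  }
})
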
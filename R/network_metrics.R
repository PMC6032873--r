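#' Build a site x period bipartite interaction matrix
#'
#' Rows are insect (hoverfly) species, columns plant taxa; cell (i, j) counts
#' the individual insects of species i whose pollen profile contains taxon j
#' at more than `presence_min_percent` percent — a presence/absence basis per
#' individual, deliberately ignoring read abundance to avoid amplification
#' biases.
#'
#' @param profiles Tidy profile table from [profile_insects()].
#' @param site,period Cell selectors.
#' @param presence_min_percent Exclusive percent threshold for counting a
#'   taxon as present on an individual (default 0: any identified read).
#' @return Integer matrix (insect species x plant taxa) with attributes
#'   `site` and `period`. Empty (0 x 0) when no profiles match.
#' @export
build_interaction_matrix <- function(profiles, site, period,
                                     presence_min_percent = 0) {
  p <- profiles[profiles$site == site & profiles$period == period &
                  profiles$percent > presence_min_percent, , drop = FALSE]
  if (nrow(p) == 0) {
    m <- matrix(integer(0), 0, 0)
  } else {
    pairs <- unique(p[, c("insect_id", "insect_species", "taxon")])
    m <- unclass(table(pairs$insect_species, pairs$taxon))
    m <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  }
  attr(m, "site") <- site
  attr(m, "period") <- period
  m
}

#' Two-dimensional Shannon entropy of an interaction matrix
#'
#' `H2 = -sum_ij p_ij log(p_ij)` with `p_ij = a_ij / m` and the convention
#' `0 log 0 = 0`. Natural logarithms throughout.
#'
#' @param mat Nonnegative matrix with positive total.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(mat) {
  m <- sum(mat)
  if (m <= 0) stop("entropy undefined for an empty matrix (m = 0)")
  p <- mat[mat > 0] / m
  -sum(p * log(p))
}

entropy_of_counts <- function(a) {
  # entropy of a nonnegative (possibly non-integer) cell vector
  m <- sum(a)
  p <- a[a > 0] / m
  -sum(p * log(p))
}

# single-unit 2x2 cycle moves that keep marginals fixed; hill-climb entropy
# in direction `sign` (+1 maximise, -1 minimise, with extreme steps when
# minimising since entropy is concave along a cycle edge)
cycle_improve <- function(a, maximise) {
  nr <- nrow(a); nc <- ncol(a)
  if (nr < 2 || nc < 2) return(a)
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 10000L) {
    improved <- FALSE
    guard <- guard + 1L
    for (i in seq_len(nr - 1)) for (i2 in (i + 1):nr)
      for (j in seq_len(nc - 1)) for (j2 in (j + 1):nc) {
        # move t along cycle: a[i,j]+t, a[i,j2]-t, a[i2,j]-t, a[i2,j2]+t
        if (maximise) {
          steps <- c(1L, -1L)
        } else {
          tmax <- min(a[i, j2], a[i2, j])
          tmin <- -min(a[i, j], a[i2, j2])
          steps <- setdiff(unique(c(tmax, tmin)), 0L)
        }
        for (t in steps) {
          if (t > 0 && (a[i, j2] < t || a[i2, j] < t)) next
          if (t < 0 && (a[i, j] < -t || a[i2, j2] < -t)) next
          b <- a
          b[i, j] <- b[i, j] + t; b[i2, j2] <- b[i2, j2] + t
          b[i, j2] <- b[i, j2] - t; b[i2, j] <- b[i2, j] - t
          if ((entropy_of_counts(b) - entropy_of_counts(a)) *
              (if (maximise) 1 else -1) > 1e-12) {
            a <- b
            improved <- TRUE
          }
        }
      }
  }
  a
}

#' Entropy extremes attainable under fixed marginals
#'
#' `H2max` comes from an even integer fill (cells initialised near
#' `A_i * C_j / m`, adjusted one unit at a time to meet the marginals) and
#' refined by 2x2 cycle-move local search, which walks the transportation
#' polytope's integer edges.
#'
#' `H2min` exploits that minimising entropy is the same as maximising the
#' separable concave-free objective `sum a log a`, whose optimum over the
#' transportation polytope sits at a vertex; every vertex arises by
#' repeatedly saturating one cell with `min(remaining A_i, remaining C_j)`,
#' so a memoised recursion over those placements yields the exact integer
#' minimum. The recursion is used up to 12 cells; beyond that, greedy
#' concentration (always saturating the cell of the largest remaining
#' marginals) plus extreme-step cycle-move descent stands in. For small
#' problems the results coincide with the exhaustive extremes of
#' [enumerate_entropy_extremes()].
#'
#' @param row_totals,col_totals Nonnegative integer marginals with equal sums.
#' @return Named numeric vector `c(H2min, H2max)`.
#' @export
h2_bounds <- function(row_totals, col_totals) {
  row_totals <- as.numeric(row_totals); col_totals <- as.numeric(col_totals)
  m <- sum(row_totals)
  if (abs(m - sum(col_totals)) > 1e-9)
    stop("inconsistent marginals: row and column totals differ")
  if (m <= 0) stop("marginals sum to zero")
  row_totals <- row_totals[row_totals > 0]
  col_totals <- col_totals[col_totals > 0]
  nr <- length(row_totals); nc <- length(col_totals)

  # --- maximum: even integer fill, repair marginals, then hill-climb
  a <- floor(outer(row_totals, col_totals) / m)
  repeat {
    drow <- row_totals - rowSums(a)
    dcol <- col_totals - colSums(a)
    if (sum(drow) == 0) break
    # add one unit to the most under-filled eligible cell
    elig <- which(outer(drow > 0, dcol > 0, "&"), arr.ind = TRUE)
    tgt <- outer(row_totals, col_totals) / m
    deficit <- (tgt - a)[elig]
    pick <- elig[which.max(deficit), , drop = FALSE]
    a[pick] <- a[pick] + 1
  }
  amax <- cycle_improve(a, maximise = TRUE)
  h2max <- entropy_of_counts(amax)

  # --- minimum: exact vertex search when small, greedy + descent otherwise
  if (nr * nc <= 12) {
    h2min <- entropy_min_exact(row_totals, col_totals)
  } else {
    b <- matrix(0, nr, nc)
    rrem <- row_totals; crem <- col_totals
    while (sum(rrem) > 0) {
      i <- which.max(rrem); j <- which.max(crem)
      amt <- min(rrem[i], crem[j])
      b[i, j] <- b[i, j] + amt
      rrem[i] <- rrem[i] - amt; crem[j] <- crem[j] - amt
    }
    bmin <- cycle_improve(b, maximise = FALSE)
    h2min <- entropy_of_counts(bmin)
  }
  c(H2min = h2min, H2max = h2max)
}

# exact minimum entropy over integer matrices with the given marginals:
# min H2 = log(m) - max(sum a log a) / m, and the maximum of the convex sum
# over the transportation polytope is attained at a vertex; all vertices are
# reachable by repeatedly saturating a cell with min(remaining row, remaining
# column). Memoised on the multisets of remaining marginals.
entropy_min_exact <- function(row_totals, col_totals) {
  memo <- new.env(parent = emptyenv())
  g <- function(rrem, crem) {
    rrem <- sort(rrem[rrem > 0], decreasing = TRUE)
    crem <- sort(crem[crem > 0], decreasing = TRUE)
    if (!length(rrem)) return(0)
    key <- paste(paste(rrem, collapse = ","), paste(crem, collapse = ","),
                 sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    seen <- character(0)
    for (i in seq_along(rrem)) for (j in seq_along(crem)) {
      pair <- paste(rrem[i], crem[j])
      if (pair %in% seen) next   # symmetric choice, same value multisets
      seen <- c(seen, pair)
      amt <- min(rrem[i], crem[j])
      r2 <- rrem; r2[i] <- r2[i] - amt
      c2 <- crem; c2[j] <- c2[j] - amt
      v <- amt * log(amt) + g(r2, c2)
      if (v > best) best <- v
    }
    memo[[key]] <- best
    best
  }
  m <- sum(row_totals)
  log(m) - g(row_totals, col_totals) / m
}

#' Network-level specialisation H2'
#'
#' Standardises the observed two-dimensional Shannon entropy against the
#' extremes attainable under the observed marginals:
#' `H2' = (H2max - H2) / (H2max - H2min)`, clipped to `[0, 1]`. 0 means
#' complete generalisation (interactions as even as the marginals allow), 1
#' complete specialisation. Degenerate networks with `H2max = H2min` (for
#' example a single cell) return 0.
#'
#' @param mat Interaction matrix with nonnegative integer entries, `m > 0`.
#' @return List of class `network_specialisation`: `H2`, `H2min`, `H2max`,
#'   `H2prime`.
#' @export
h2_prime <- function(mat) {
  mat <- mat[rowSums(mat) > 0, colSums(mat) > 0, drop = FALSE]
  h2 <- shannon_entropy(mat)
  b <- h2_bounds(rowSums(mat), colSums(mat))
  denom <- b[["H2max"]] - b[["H2min"]]
  h2p <- if (denom > 1e-12) (b[["H2max"]] - h2) / denom else 0
  structure(list(H2 = h2, H2min = b[["H2min"]], H2max = b[["H2max"]],
                 H2prime = min(1, max(0, h2p))),
            class = "network_specialisation")
}

# integer allocation of A units over partners with availability q minimising
# KL(n/A || q): largest-remainder start, then single-unit exchange descent
min_kl_allocation <- function(A, q) {
  kl <- function(n) {
    p <- n / A
    sum(ifelse(p > 0, p * log(p / q), 0))
  }
  n <- floor(A * q)
  while (sum(n) < A) {
    # add the unit where the KL increment is smallest
    cand <- which(q > 0)
    inc <- vapply(cand, function(j) { n2 <- n; n2[j] <- n2[j] + 1; kl(n2) },
                  numeric(1))
    n[cand[which.min(inc)]] <- n[cand[which.min(inc)]] + 1
  }
  repeat {
    cur <- kl(n)
    best <- NULL; bestv <- cur
    for (j in which(n > 0)) for (j2 in which(q > 0)) {
      if (j == j2) next
      n2 <- n; n2[j] <- n2[j] - 1; n2[j2] <- n2[j2] + 1
      v <- kl(n2)
      if (v < bestv - 1e-12) { best <- n2; bestv <- v }
    }
    if (is.null(best)) break
    n <- best
  }
  n
}

#' Species-level specialisation d'
#'
#' For each insect species (row) with positive total, `d` is the
#' Kullback–Leibler divergence of the row's interaction proportions from the
#' overall partner availability `q_j = C_j / m`. It is standardised as
#' `d' = (d - dmin) / (dmax - dmin)` with `dmax = log(m / A_i)` (all
#' interactions on the rarest possible exclusive partner) and `dmin` the
#' minimum divergence over integer allocations of the row total across
#' partners (largest-remainder allocation refined by unit exchanges).
#' Species absent from the matrix (zero row total) are omitted.
#'
#' @param mat Interaction matrix with row/column names.
#' @param species Optional subset of row names.
#' @return Data.frame `species`, `row_total` (interactions `A_i`), `d`,
#'   `dmin`, `dmax`, `dprime`, of class `species_specialisation`.
#' @export
d_prime <- function(mat, species = NULL) {
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  m <- sum(mat)
  if (m <= 0) stop("d' undefined for an empty matrix")
  q <- colSums(mat) / m
  rows <- if (is.null(species)) rownames(mat) else species
  rows <- rows[rows %in% rownames(mat)]
  out <- list()
  for (r in rows) {
    A <- sum(mat[r, ])
    if (A == 0) next  # species absent in this period are omitted, not zero
    p <- mat[r, ] / A
    d <- sum(ifelse(p > 0, p * log(p / q), 0))
    dmax <- log(m / A)
    dmin <- {
      n <- min_kl_allocation(A, q)
      pn <- n / A
      sum(ifelse(pn > 0, pn * log(pn / q), 0))
    }
    denom <- dmax - dmin
    dp <- if (denom > 1e-12) (d - dmin) / denom else 0
    out[[r]] <- data.frame(species = r, row_total = A, d = d, dmin = dmin,
                           dmax = dmax, dprime = min(1, max(0, dp)),
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(species = character(0), row_total = integer(0), d = numeric(0),
               dmin = numeric(0), dmax = numeric(0), dprime = numeric(0),
               stringsAsFactors = FALSE)
  class(res) <- c("species_specialisation", "data.frame")
  res
}

#' Exhaustive entropy extremes over all matrices with given marginals
#'
#' Test oracle: enumerates every nonnegative integer matrix with the stated
#' row and column totals and returns the exact minimum and maximum of the
#' two-dimensional Shannon entropy. Refuses totals above `max_m`
#' interactions, where exhaustive enumeration stops being practical.
#'
#' @param row_totals,col_totals Nonnegative integer marginals with equal sums.
#' @param max_m Enumeration cap on the total (default 12).
#' @return Named numeric vector `c(min, max)`.
#' @export
enumerate_entropy_extremes <- function(row_totals, col_totals, max_m = 12) {
  m <- sum(row_totals)
  if (m != sum(col_totals)) stop("inconsistent marginals")
  if (m > max_m) stop("total exceeds the enumeration cap (m = ", m, ")")
  row_totals <- row_totals[row_totals > 0]
  col_totals <- col_totals[col_totals > 0]
  hmin <- Inf; hmax <- -Inf
  nr <- length(row_totals); nc <- length(col_totals)
  # recursively fill row by row; each row is a composition of its total
  # bounded by the remaining column capacity
  compositions <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps) return(list(total)) else return(list())
    }
    out <- list()
    for (x in 0:min(total, caps[1])) {
      for (rest in compositions(total - x, caps[-1]))
        out[[length(out) + 1L]] <- c(x, rest)
    }
    out
  }
  recurse <- function(rowi, crem, acc) {
    if (rowi > nr) {
      h <- entropy_of_counts(acc)
      hmin <<- min(hmin, h); hmax <<- max(hmax, h)
      return(invisible())
    }
    for (comp in compositions(row_totals[rowi], crem))
      recurse(rowi + 1L, crem - comp, c(acc, comp))
  }
  recurse(1L, col_totals, numeric(0))
  c(min = hmin, max = hmax)
}

#' Network metrics table across site x period cells
#'
#' Computes H2' and per-species d' for every site x period combination in the
#' profile table, laid out one row per species per cell with the network H2'
#' repeated, mirroring how network and species specialisation are usually
#' tabulated together. `n` counts the individual insects of the species in
#' the cell.
#'
#' @param profiles Tidy profile table from [profile_insects()].
#' @param presence_min_percent Passed to [build_interaction_matrix()].
#' @return Data.frame `site`, `period`, `H2prime`, `species`, `n`, `dprime`.
#' @export
network_metrics_table <- function(profiles, presence_min_percent = 0) {
  cells <- unique(profiles[, c("site", "period")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    s <- cells$site[i]; p <- cells$period[i]
    mat <- build_interaction_matrix(profiles, s, p, presence_min_percent)
    if (sum(mat) == 0) next
    h <- h2_prime(mat)
    dd <- d_prime(mat)
    sub <- profiles[profiles$site == s & profiles$period == p, ]
    n_ind <- tapply(sub$insect_id, sub$insect_species,
                    function(x) length(unique(x)))
    out[[length(out) + 1L]] <- data.frame(
      site = s, period = p, H2prime = h$H2prime,
      species = dd$species, n = as.integer(n_ind[dd$species]),
      dprime = dd$dprime, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(site = character(0), period = character(0),
               H2prime = numeric(0), species = character(0), n = integer(0),
               dprime = numeric(0), stringsAsFactors = FALSE)
}
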
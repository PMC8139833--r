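#' LAD annotation container
#'
#' Sorted, non-overlapping, half-open base-pair intervals marking the
#' lamina-associated domains of one chromosome.
#'
#' @param intervals two-column matrix (start_bp, end_bp), 0-based half-open.
#' @param chromosome_length_bp chromosome length; defaults to the last end.
#' @return an object of class `lad_annotation`.
#' @export
lad_annotation <- function(intervals, chromosome_length_bp = NULL) {
  intervals <- matrix(as.numeric(intervals), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  if (nrow(intervals)) {
    if (any(intervals < 0) || any(intervals[, 2] <= intervals[, 1]))
      stop("intervals must satisfy 0 <= start < end")
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (nrow(intervals) > 1 &&
        any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
      stop("intervals must be pairwise disjoint")
  }
  if (is.null(chromosome_length_bp))
    chromosome_length_bp <- if (nrow(intervals)) max(intervals[, 2]) else 0
  if (nrow(intervals) && chromosome_length_bp < max(intervals[, 2]))
    stop("chromosome_length_bp shorter than the annotation")
  structure(list(intervals = intervals,
                 chromosome_length_bp = as.numeric(chromosome_length_bp)),
            class = "lad_annotation")
}

#' @export
print.lad_annotation <- function(x, ...) {
  n <- nrow(x$intervals)
  cov <- if (n) sum(x$intervals[, 2] - x$intervals[, 1]) else 0
  cat(sprintf("<lad_annotation> %d domain(s), %.3g bp covered of %.3g bp (%.1f%%)\n",
              n, cov, x$chromosome_length_bp,
              if (x$chromosome_length_bp > 0) 100 * cov / x$chromosome_length_bp else 0))
  invisible(x)
}

#' Read LAD intervals from a BED-like source
#'
#' Accepts minimal 3-column BED (`chrom<TAB>start<TAB>end`, 0-based
#' half-open).  Intervals are sorted and touching/overlapping intervals are
#' unioned (via `IRanges::reduce`), matching the convention that adjacent
#' LAD segments form one domain.
#'
#' @param con a file path, a connection, or a character vector of lines.
#' @param chromosome_length_bp optional chromosome length.
#' @return a [lad_annotation()].
#' @export
read_lad_intervals <- function(con, chromosome_length_bp = NULL) {
  lines <- if (is.character(con) && length(con) == 1L && file.exists(con))
    readLines(con) else if (inherits(con, "connection")) readLines(con) else con
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (!length(lines))
    return(lad_annotation(matrix(numeric(0), ncol = 2), chromosome_length_bp))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  starts <- ends <- numeric(length(lines))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop("parse error at line ", i, ": expected chrom<TAB>start<TAB>end")
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("parse error at line ", i, ": non-numeric coordinates")
    if (e <= s)
      stop("parse error at line ", i, ": end <= start")
    starts[i] <- s; ends[i] <- e
  }
  # merge in 1-based closed coordinates; reduce() unions touching intervals
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1, end = ends))
  merged <- cbind(IRanges::start(ir) - 1, IRanges::end(ir))
  lad_annotation(merged, chromosome_length_bp)
}

#' Map LAD intervals to per-bead type labels
#'
#' Bead `i` (0-based) covers base pairs `[i*bp_per_bead, (i+1)*bp_per_bead)`
#' and is labelled LAD when at least half of its base pairs fall in LAD
#' intervals (ties label LAD).  Beads beyond the annotation are non-LAD.
#'
#' @param annotation a [lad_annotation()].
#' @param n_beads number of beads.
#' @param bp_per_bead base pairs per bead.
#' @return a factor vector of length `n_beads` with levels `nonLAD`, `LAD`.
#' @export
intervals_to_bead_labels <- function(annotation, n_beads, bp_per_bead = 600) {
  stopifnot(inherits(annotation, "lad_annotation"), n_beads >= 0,
            bp_per_bead > 0)
  cov <- numeric(n_beads)
  iv <- annotation$intervals
  if (nrow(iv)) for (r in seq_len(nrow(iv))) {
    s <- iv[r, 1]; e <- iv[r, 2]
    b0 <- max(0, floor(s / bp_per_bead))
    b1 <- min(n_beads - 1, floor((e - 1) / bp_per_bead))
    if (b1 < b0) next
    b <- b0:b1
    cov[b + 1] <- cov[b + 1] +
      pmin(e, (b + 1) * bp_per_bead) - pmax(s, b * bp_per_bead)
  }
  factor(ifelse(cov >= bp_per_bead / 2, "LAD", "nonLAD"),
         levels = c("nonLAD", "LAD"))
}

#' Synthesize a random LAD/non-LAD block pattern
#'
#' Draws alternating LAD and non-LAD blocks with geometrically distributed
#' lengths: LAD blocks have mean `mean_domain_beads` and non-LAD blocks mean
#' `mean_domain_beads * (1 - f) / f`, so the realized LAD fraction converges
#' to `lad_fraction` for long chains.  This emulates the observed domain
#' statistics of a real annotation (e.g. 48% LAD with 90 kbp = 150-bead mean
#' domains) while randomizing domain placement.
#'
#' @param n_beads number of beads.
#' @param lad_fraction target LAD fraction f, in [0, 1].
#' @param mean_domain_beads mean LAD block length in beads (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return a factor vector of length `n_beads` (levels `nonLAD`, `LAD`).
#' @export
synthesize_lad_pattern <- function(n_beads, lad_fraction = 0.48,
                                   mean_domain_beads = 150, seed = NULL) {
  if (lad_fraction < 0 || lad_fraction > 1)
    stop("invalid parameter: lad_fraction must lie in [0, 1]")
  stopifnot(mean_domain_beads >= 1, n_beads >= 0)
  lev <- c("nonLAD", "LAD")
  if (n_beads == 0) return(factor(character(0), levels = lev))
  if (lad_fraction == 0) return(factor(rep("nonLAD", n_beads), levels = lev))
  if (lad_fraction == 1) return(factor(rep("LAD", n_beads), levels = lev))
  mean_non <- mean_domain_beads * (1 - lad_fraction) / lad_fraction
  with_seed(seed, {
    out <- integer(0)
    is_lad <- runif(1) < lad_fraction
    while (length(out) < n_beads) {
      m <- if (is_lad) mean_domain_beads else mean_non
      len <- rgeom(1, prob = 1 / m) + 1L
      out <- c(out, rep(if (is_lad) 1L else 0L, len))
      is_lad <- !is_lad
    }
    factor(lev[out[seq_len(n_beads)] + 1L], levels = lev)
  })
}

#' Select the bondable subset of LAD beads
#'
#' Flags exactly `round(psi * n_LAD)` LAD beads, chosen uniformly at random,
#' as eligible for lamina bonding.  Non-LAD beads are never flagged.
#'
#' @param bead_type factor/character vector of bead types (`LAD`/`nonLAD`).
#' @param psi bondable fraction in [0, 1].
#' @param seed optional integer seed.
#' @return a logical vector of the same length.
#' @export
select_bondable <- function(bead_type, psi, seed = NULL) {
  if (psi < 0 || psi > 1) stop("invalid parameter: psi must lie in [0, 1]")
  lad_idx <- which(bead_type == "LAD")
  k <- round(psi * length(lad_idx))
  out <- logical(length(bead_type))
  if (k > 0)
    out[with_seed(seed, sample(lad_idx, k))] <- TRUE
  out
}

#' Initial chain configuration inside the nucleus
#'
#' A compact, self-intersecting random walk with fixed step `rest_length`,
#' confined to radius `confinement_radius - rest_length` and recentred so
#' the chain's centre of mass sits at the nuclear centre.  Overlaps between
#' non-consecutive beads are tolerated here and removed by the soft
#' push-off stage of [equilibrate_protocol()].
#'
#' @param n_beads number of beads.
#' @param confinement_radius nucleus radius (sigma units).
#' @param rest_length step length between consecutive beads.
#' @param seed optional integer seed; fixed seeds give identical walks.
#' @return an `n_beads` x 3 matrix of positions.
#' @export
initial_configuration <- function(n_beads, confinement_radius,
                                  rest_length = 1, seed = NULL) {
  if (n_beads * (rest_length / 2)^3 >= confinement_radius^3)
    stop("infeasible-geometry: chain cannot fit in the confinement sphere")
  rmax <- confinement_radius - rest_length / 2
  if (rmax <= rest_length)
    stop("infeasible-geometry: confinement radius smaller than one bead")
  with_seed(seed, {
    for (attempt in 1:500) {
      pos <- matrix(0, n_beads, 3)
      for (i in seq_len(n_beads)[-1]) {
        repeat {
          u <- rnorm(3)
          step <- u / sqrt(sum(u^2)) * rest_length
          cand <- pos[i - 1, ] + step
          if (sum(cand^2) <= rmax^2) break
        }
        pos[i, ] <- cand
      }
      com <- colMeans(pos)
      centred <- sweep(pos, 2, com)
      # exact recentring when it stays inside; otherwise accept walks whose
      # centre of mass already sits close enough to the origin
      if (max(rowSums(centred^2)) <= rmax^2) return(centred)
      if (sum(com^2) <= (0.05 * confinement_radius)^2) return(pos)
    }
    stop("infeasible-geometry: could not centre the chain inside the nucleus")
  })
}

#' Chromatin chain container
#'
#' @param positions N x 3 matrix of bead positions.
#' @param bead_type per-bead type (`LAD`/`nonLAD`).
#' @param bondable per-bead logical bonding eligibility (LAD only).
#' @return an object of class `chromatin_chain`.
#' @export
chromatin_chain <- function(positions, bead_type, bondable = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  bead_type <- factor(as.character(bead_type), levels = c("nonLAD", "LAD"))
  stopifnot(length(bead_type) == n, !anyNA(bead_type))
  if (is.null(bondable)) bondable <- logical(n)
  stopifnot(length(bondable) == n)
  if (any(bondable & bead_type != "LAD"))
    stop("bondable beads must be LAD beads")
  structure(list(positions = positions, bead_type = bead_type,
                 bondable = bondable, n_beads = n),
            class = "chromatin_chain")
}

#' @export
print.chromatin_chain <- function(x, ...) {
  cat(sprintf("<chromatin_chain> N = %d | %.1f%% LAD | %d bondable\n",
              x$n_beads, 100 * mean(x$bead_type == "LAD"), sum(x$bondable)))
  invisible(x)
}

#' Build a chromatin chain from parameters
#'
#' Convenience constructor: bead types from an annotation (or the synthetic
#' block generator when none is given), psi-limited bonding eligibility, and
#' an initial random-walk configuration centred in the nucleus.
#'
#' @param params a [sim_params()] object (must be confined for the initial
#'   configuration; unconfined chains start from a free random walk).
#' @param annotation optional [lad_annotation()]; when `NULL` a synthetic
#'   pattern with `lad_fraction` and `mean_domain_beads` is drawn.
#' @param lad_fraction,mean_domain_beads synthetic-pattern statistics.
#' @param seed integer seed controlling pattern, eligibility and initial
#'   configuration; defaults to `params$rng_seed`.
#' @return a [chromatin_chain()].
#' @export
build_chain <- function(params, annotation = NULL, lad_fraction = 0.48,
                        mean_domain_beads = 150, seed = params$rng_seed) {
  n <- params$n_beads
  types <- if (is.null(annotation))
    synthesize_lad_pattern(n, lad_fraction, mean_domain_beads, seed = seed)
  else
    intervals_to_bead_labels(annotation, n, params$bp_per_bead)
  bondable <- select_bondable(types, params$psi, seed = seed + 1L)
  pos <- if (!is.null(params$confinement_radius))
    initial_configuration(n, params$confinement_radius, params$rest_length,
                          seed = seed + 2L)
  else
    free_walk(n, params$rest_length, seed = seed + 2L)
  chromatin_chain(pos, types, bondable)
}

# internal: unconfined self-avoiding chain grown by rejection sampling
# (directions re-drawn until the new bead clears all previous beads by
# min_sep; short backtracks resolve dead ends).  Used as the initial state
# for unconfined excluded-volume measurements, where a plain random walk
# would need very long relaxation to swell to self-avoiding statistics.
grow_saw <- function(n_beads, rest_length = 1, min_sep = 0.9, n_try = 40L,
                     seed = NULL) {
  with_seed(seed, {
    pos <- matrix(NA_real_, n_beads, 3)
    pos[1, ] <- 0
    i <- 2L
    guard <- 0L
    while (i <= n_beads) {
      guard <- guard + 1L
      if (guard > 50L * n_beads)
        stop("chain growth failed to place all beads")
      placed <- FALSE
      for (t in seq_len(n_try)) {
        u <- rnorm(3)
        cand <- pos[i - 1L, ] + u / sqrt(sum(u^2)) * rest_length
        ok <- i == 2L ||
          all(colSums((t(pos[seq_len(i - 2L), , drop = FALSE]) - cand)^2) >=
              (min_sep * rest_length)^2)
        if (ok) {
          pos[i, ] <- cand
          i <- i + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) i <- max(2L, i - 6L)   # back out of a dead end
    }
    sweep(pos, 2, colMeans(pos))
  })
}

# internal: athermal pivot moves on a self-avoiding configuration.  Rotating
# the chain tail about a random bead equilibrates the global conformation in
# O(N) accepted moves; overlap rejection keeps all non-bonded pairs at least
# min_sep apart.  Complements grow_saw, whose chain-growth ensemble is
# biased toward compact conformations.
pivot_saw <- function(pos, n_accept = 300L, rest_length = 1, min_sep = 0.9,
                      seed = NULL) {
  n <- nrow(pos)
  lim2 <- (min_sep * rest_length)^2
  with_seed(seed, {
    acc <- 0L
    for (try in seq_len(60L * n_accept)) {
      if (acc >= n_accept) break
      k <- sample(2:(n - 1), 1)
      ax <- rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      th <- runif(1, 0, 2 * pi)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      tail_idx <- (k + 1):n
      newtail <- sweep(sweep(pos[tail_idx, , drop = FALSE], 2, pos[k, ]) %*%
                         t(R), 2, pos[k, ], FUN = "+")
      head <- pos[seq_len(k - 1), , drop = FALSE]
      d2 <- outer(rowSums(head^2), rowSums(newtail^2), "+") -
        2 * head %*% t(newtail)
      if (min(d2) >= lim2) {
        pos[tail_idx, ] <- newtail
        acc <- acc + 1L
      }
    }
    sweep(pos, 2, colMeans(pos))
  })
}

# internal: unconfined random walk with fixed step
free_walk <- function(n_beads, rest_length = 1, seed = NULL) {
  with_seed(seed, {
    u <- matrix(rnorm(3 * (n_beads - 1)), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * rest_length
    pos <- rbind(0, apply(u, 2, cumsum))
    sweep(pos, 2, colMeans(pos))
  })
}

#' Export bead labels as a two-column table
#'
#' @param chain a [chromatin_chain()].
#' @param path optional CSV path; when `NULL` the data frame is returned.
#' @return (invisibly) a data frame `(bead_index, type)`, 0-based indices.
#' @export
bead_labels_table <- function(chain, path = NULL) {
  df <- data.frame(bead_index = seq_len(chain$n_beads) - 1L,
                   type = as.character(chain$bead_type))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
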
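# Moore-neighbour boundary tracing of a single-particle mask.
# Returns the traced contour length with unit steps for orthogonal moves
# and sqrt(2) for diagonal moves.
.trace_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(4)
  ord <- order(idx[, 1], idx[, 2])
  sr <- idx[ord[1], 1]; sc <- idx[ord[1], 2]
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)   # clockwise from W
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  cr <- sr; cc <- sc
  bdir <- 1L  # start pixel is topmost-leftmost, so its W neighbour is background
  per <- 0
  nsteps <- 0L
  maxsteps <- 8L * nrow(idx) + 8L
  d1 <- 0L  # direction of the very first move; trace closes when the
            # start -> first-pixel edge is about to be traversed again
  repeat {
    nxt <- 0L
    for (k in 1:8) {
      d <- ((bdir - 1L + k - 1L) %% 8L) + 1L
      if (m[cr + dr[d], cc + dc[d]]) { nxt <- d; break }
    }
    if (nxt == 0L) return(4)  # isolated pixel
    if (nsteps > 0L && cr == sr && cc == sc && nxt == d1) break
    if (nsteps == 0L) d1 <- nxt
    prevd <- ((nxt - 2L) %% 8L) + 1L
    pr <- cr + dr[prevd]; pc <- cc + dc[prevd]
    per <- per + if (dr[nxt] != 0L && dc[nxt] != 0L) sqrt(2) else 1
    cr <- cr + dr[nxt]; cc <- cc + dc[nxt]
    bdir <- which(dr == (pr - cr) & dc == (pc - cc))
    nsteps <- nsteps + 1L
    if (nsteps > maxsteps) break
  }
  per
}

#' Shape descriptors for labelled particles
#'
#' Computes, per positive label, the descriptor set used for mitochondrial
#' particle quantification: area (pixel count x pixel area), major and
#' minor axis of the moment-equivalent ellipse (from the second central
#' moments of the pixel coordinates), perimeter (Moore-neighbour contour
#' trace, sqrt(2)-weighted diagonals) and circularity
#' \eqn{4\pi A / P^2} clamped to (0, 1].
#'
#' @param label_grid integer matrix; 0 = background, positive values label
#'   particles.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param exclude_border drop particles touching the grid border (their
#'   truncated shapes bias descriptors); default TRUE.
#' @param min_pixels particles smaller than this many pixels are skipped
#'   with a warning (default 5).
#' @return data.frame with columns `particle`, `n_pixels`, `area_um2`,
#'   `major_um`, `minor_um`, `axis_ratio`, `perimeter_um`, `circularity`.
#' @export
shape_descriptors <- function(label_grid, pixel_size_um,
                              exclude_border = TRUE, min_pixels = 5L) {
  g <- as.matrix(label_grid)
  if (any(g < 0) || any(g != round(g))) stop("labels must be non-negative integers")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  labels <- sort(unique(g[g > 0]))
  rows <- lapply(labels, function(lb) {
    px <- which(g == lb, arr.ind = TRUE)
    if (nrow(px) < min_pixels) {
      warning("label ", lb, " has fewer than ", min_pixels, " pixels; skipped")
      return(NULL)
    }
    if (exclude_border &&
        (any(px[, 1] %in% c(1L, nrow(g))) || any(px[, 2] %in% c(1L, ncol(g)))))
      return(NULL)
    n <- nrow(px)
    area <- n * pixel_size_um^2
    xc <- px[, 2] - mean(px[, 2])
    yc <- px[, 1] - mean(px[, 1])
    cxx <- mean(xc^2); cyy <- mean(yc^2); cxy <- mean(xc * yc)
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1]) * pixel_size_um
    minor <- 4 * sqrt(ev[2]) * pixel_size_um
    rmin <- min(px[, 1]); rmax <- max(px[, 1])
    cmin <- min(px[, 2]); cmax <- max(px[, 2])
    sub <- g[rmin:rmax, cmin:cmax, drop = FALSE] == lb
    per <- .trace_perimeter(sub) * pixel_size_um
    circ <- min(4 * pi * area / per^2, 1)
    data.frame(particle = lb, n_pixels = n, area_um2 = area,
               major_um = major, minor_um = minor,
               axis_ratio = if (minor > 0) major / minor else Inf,
               perimeter_um = per, circularity = circ)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(particle = integer(), n_pixels = integer(),
                      area_um2 = numeric(), major_um = numeric(),
                      minor_um = numeric(), axis_ratio = numeric(),
                      perimeter_um = numeric(), circularity = numeric())
  row.names(out) <- NULL
  out
}

#' Classify particles as elongated, enlarged or other
#'
#' A particle is elongated when its major/minor axis ratio exceeds
#' `ratio_threshold` (strict); otherwise enlarged when circularity exceeds
#' `circ_threshold` and area exceeds `area_threshold` (both strict);
#' otherwise other. Elongation takes precedence so the classes are
#' disjoint.
#'
#' @param records data.frame from [shape_descriptors()].
#' @param ratio_threshold major/minor axis ratio bound (default 3).
#' @param circ_threshold circularity bound (default 0.8).
#' @param area_threshold area bound in square micrometres (default 0.5).
#' @return `records` with an added `class` column.
#' @export
classify_particles <- function(records, ratio_threshold = 3,
                               circ_threshold = 0.8, area_threshold = 0.5) {
  cls <- ifelse(records$axis_ratio > ratio_threshold, "elongated",
         ifelse(records$circularity > circ_threshold &
                records$area_um2 > area_threshold, "enlarged", "other"))
  records$class <- cls
  records
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when both samples have at most `exact_max` observations: the
#' two-sided p-value is the fraction of all \eqn{C(n_1+n_2, n_1)} group
#' assignments whose U statistic deviates from its null mean
#' \eqn{n_1 n_2 / 2} at least as much as the observed one (ties handled
#' by mid-ranks throughout). Larger samples use the normal approximation
#' with the tie-corrected variance.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest per-group size for full enumeration
#'   (default 8).
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  all_v <- c(x, y)
  rk <- rank(all_v, ties.method = "average")
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(U_obs - mu)
    devs <- apply(combos, 2, function(ix) {
      abs(sum(rk[ix]) - n1 * (n1 + 1) / 2 - mu)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    return(list(U = U_obs, p = p, method = "exact"))
  }
  N <- n1 + n2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) return(list(U = U_obs, p = 1, method = "normal"))
  z <- (U_obs - mu) / sqrt(v)
  list(U = U_obs, p = 2 * stats::pnorm(-abs(z)), method = "normal")
}

#' Per-field class counts and between-condition comparison
#'
#' Counts elongated / enlarged / other particles per field and compares
#' the per-field elongated and enlarged counts between two conditions
#' with the two-sided Mann-Whitney test (exact for up to 8 fields per
#' condition).
#'
#' @param records classified particle records with a `field_id` column.
#' @param group_map data.frame with columns `field_id`, `condition`
#'   (exactly two conditions).
#' @return list with `counts` (per-field data.frame) and `tests`
#'   (one row per class: `class`, `U`, `p`, `method`).
#' @export
field_summary <- function(records, group_map) {
  conds <- unique(group_map$condition)
  if (length(conds) != 2) stop("need exactly two conditions")
  fields <- group_map$field_id
  counts <- do.call(rbind, lapply(fields, function(f) {
    rc <- records[records$field_id == f, ]
    data.frame(field_id = f,
               condition = group_map$condition[group_map$field_id == f],
               elongated = sum(rc$class == "elongated"),
               enlarged = sum(rc$class == "enlarged"),
               other = sum(rc$class == "other"),
               total = nrow(rc), stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(c("elongated", "enlarged"), function(cl) {
    xa <- counts[counts$condition == conds[1], cl]
    xb <- counts[counts$condition == conds[2], cl]
    if (length(xa) < 3 || length(xb) < 3) {
      return(data.frame(class = cl, U = NA_real_, p = NA_real_,
                        method = "insufficient fields",
                        stringsAsFactors = FALSE))
    }
    mt <- mann_whitney_test(xa, xb)
    data.frame(class = cl, U = mt$U, p = mt$p, method = mt$method,
               stringsAsFactors = FALSE)
  }))
  row.names(counts) <- row.names(tests) <- NULL
  list(counts = counts, tests = tests)
}
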
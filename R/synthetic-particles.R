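#' Generate labelled fields of elliptical particles with known classes
#'
#' Rasterizes non-overlapping ellipses onto integer label grids. Each
#' particle's continuous parameters are drawn to satisfy its class under
#' the morphology rules: elongated particles have a major/minor axis
#' ratio well above 3, enlarged particles are near-circular with area
#' well above 0.5 um^2, and "other" particles satisfy neither (their area
#' stays below 0.5 um^2). Placement is rejection sampling with a capped
#' number of attempts.
#'
#' @param n_fields number of fields (micrograph stand-ins).
#' @param particles_per_field particles rasterized per field.
#' @param class_mix length-3 numeric, fractions of
#'   elongated / enlarged / other (must sum to 1).
#' @param pixel_size_um pixel edge length in micrometres (default 0.02).
#' @param field_um field edge length in micrometres (default 12).
#' @param seed integer seed.
#' @param max_attempts placement attempts per particle before erroring
#'   (default 10000).
#' @return list with `grids` (list of integer label matrices, one per
#'   field) and `truth` (data.frame `field_id`, `particle`, `class`,
#'   `area_um2`, `major_um`, `minor_um`, `theta`).
#' @export
gen_particle_field <- function(n_fields = 6, particles_per_field = 12,
                               class_mix = c(elongated = 1/3,
                                             enlarged = 1/3,
                                             other = 1/3),
                               pixel_size_um = 0.02, field_um = 12,
                               seed = 1, max_attempts = 10000) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class fractions must sum to 1")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  set.seed(as.integer(seed))
  npx <- round(field_um / pixel_size_um)
  classes <- c("elongated", "enlarged", "other")
  # deterministic class allocation: floor then largest remainders
  nf <- floor(class_mix * particles_per_field)
  rem <- particles_per_field - sum(nf)
  if (rem > 0) {
    o <- order(class_mix * particles_per_field - nf, decreasing = TRUE)
    nf[o[seq_len(rem)]] <- nf[o[seq_len(rem)]] + 1
  }
  class_seq <- rep(classes, nf)
  grids <- vector("list", n_fields)
  truth <- list()
  for (f in seq_len(n_fields)) {
    g <- matrix(0L, npx, npx)
    placed <- data.frame(cx = numeric(), cy = numeric(), a = numeric())
    for (i in seq_along(class_seq)) {
      cl <- class_seq[i]
      par <- switch(cl,
        elongated = list(ratio = stats::runif(1, 3.5, 6),
                         area = stats::runif(1, 0.2, 0.8)),
        enlarged = list(ratio = stats::runif(1, 1.0, 1.3),
                        area = stats::runif(1, 0.7, 1.4)),
        other = list(ratio = stats::runif(1, 1.2, 2.2),
                     area = stats::runif(1, 0.10, 0.40)))
      a_um <- sqrt(par$area * par$ratio / pi)   # semi-major, um
      b_um <- a_um / par$ratio
      theta <- stats::runif(1, 0, pi)
      a_px <- a_um / pixel_size_um
      margin <- ceiling(a_px) + 2L
      if (2L * margin >= npx)
        stop("field of ", npx, " px too small for a particle of semi-major ",
             round(a_px), " px")
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        cx <- stats::runif(1, margin, npx - margin)
        cy <- stats::runif(1, margin, npx - margin)
        if (!nrow(placed) ||
            all(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) >
                a_px + placed$a + 2)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place particle ", i, " in field ", f,
             " after ", max_attempts, " attempts; enlarge the field")
      rows <- max(1L, floor(cy - a_px - 1)):min(npx, ceiling(cy + a_px + 1))
      cols <- max(1L, floor(cx - a_px - 1)):min(npx, ceiling(cx + a_px + 1))
      ct <- cos(theta); st <- sin(theta)
      for (r in rows) {
        dx <- cols - cx
        dy <- r - cy
        u <- dx * ct + dy * st
        v <- -dx * st + dy * ct
        inside <- (u / (a_um / pixel_size_um))^2 +
                  (v / (b_um / pixel_size_um))^2 <= 1
        g[r, cols[inside]] <- i
      }
      placed <- rbind(placed, data.frame(cx = cx, cy = cy, a = a_px))
      truth[[length(truth) + 1L]] <- data.frame(
        field_id = sprintf("field%02d", f), particle = i, class = cl,
        area_um2 = par$area, major_um = 2 * a_um, minor_um = 2 * b_um,
        theta = theta, stringsAsFactors = FALSE)
    }
    grids[[f]] <- g
  }
  names(grids) <- sprintf("field%02d", seq_len(n_fields))
  list(grids = grids, truth = do.call(rbind, truth))
}
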
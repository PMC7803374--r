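#' Fraction of the cornea occupied by labeled (limbus-derived) cells
#'
#' @param state a `tissue_state`.
#' @return Fraction in `[0, 1]`.
#' @export
renewed_fraction <- function(state) {
  ids <- state$grid$cornea_ids
  mean(!is.na(state$clone[ids]))
}

#' Mean depth of the renewed-cell front
#'
#' The cornea is split into `n_sectors` angular sectors; in each sector the
#' front is the length of the contiguous run of unit-depth bins, measured
#' inward from the limbus, in which every populated bin contains at least one
#' labeled cell (bins that happen to hold no site in a narrow sector are
#' passed through). The front depth is the mean over sectors: 0 for an
#' unlabeled cornea, `R` when fully renewed.
#'
#' @param state a `tissue_state`.
#' @param n_sectors number of angular sectors.
#' @return Mean front depth in cell units.
#' @export
front_depth <- function(state, n_sectors = 64) {
  g <- state$grid
  ids <- g$cornea_ids
  depth <- g$R - g$sites$r[ids]
  sector <- pmin(floor(g$sites$theta[ids] / (2 * pi / n_sectors)), n_sectors - 1)
  labeled <- !is.na(state$clone[ids])
  nb <- max(1, ceiling(g$R))
  bin <- pmin(floor(depth), nb - 1)

  # per (sector, bin): does the bin exist, and does it hold a labeled cell?
  present <- labeled_bin <- matrix(FALSE, nb, n_sectors)
  present[cbind(bin + 1, sector + 1)] <- TRUE
  lab_idx <- cbind(bin + 1, sector + 1)[labeled, , drop = FALSE]
  labeled_bin[lab_idx] <- TRUE

  depths <- numeric(n_sectors)
  for (s in seq_len(n_sectors)) {
    d <- 0
    for (b in seq_len(nb)) {
      if (present[b, s] && !labeled_bin[b, s]) break
      d <- b
    }
    depths[s] <- d
  }
  mean(pmin(depths, g$R))
}

#' Normalized time of first full renewal
#'
#' @param trajectory a `trajectory` from [run_simulation()].
#' @return Renewal time in corneal replication times; `NA` (with a warning)
#'   when the trajectory stalled before full renewal.
#' @export
renewal_time <- function(trajectory) {
  rt <- trajectory$renewal_tnorm
  if (is.null(rt) || is.na(rt)) {
    idx <- which(trajectory$checkpoints$renewed_fraction >= 1)
    if (length(idx)) return(trajectory$checkpoints$tnorm[idx[1]])
    warning("trajectory did not reach full renewal (stop reason: ",
            trajectory$stop_reason, ")", call. = FALSE)
    return(NA_real_)
  }
  rt
}

# unmixing of a single unit annulus: labels of labeled sites ordered by theta
unmixing_annulus <- function(labels, theta) {
  ord <- order(theta)
  lab <- labels[ord]
  n_clones <- length(unique(lab))
  runs <- rle(lab)$lengths
  n_runs <- length(runs)
  if (n_runs > 1 && lab[1] == lab[length(lab)]) n_runs <- n_runs - 1  # circular
  n_clones / n_runs
}

#' Clonal unmixing order parameter
#'
#' Quantifies how well clone labels form contiguous angular stripes within a
#' radial band. For each unit-width annulus in the band, the labeled sites are
#' ordered circularly by angle and the statistic is
#' `(number of distinct clones) / (number of circular runs of equal labels)`,
#' averaged over annuli: 1 for perfect stripes (each clone a single
#' contiguous arc), decaying toward 0 for angularly mixed labels.
#'
#' @param state a `tissue_state`.
#' @param band radial interval `c(r_lo, r_hi)` in cell units (distance from
#'   the tissue centre). Default: the annulus of width 10 centred halfway to
#'   the centre, `R/2 +- 5`.
#' @param min_labeled minimum number of labeled sites in the band; below
#'   this the statistic is undefined and `NA` is returned.
#' @return Unmixing value in `[0, 1]`, or `NA`.
#' @export
unmixing <- function(state, band = NULL, min_labeled = 8) {
  g <- state$grid
  if (is.null(band)) band <- c(g$R / 2 - 5, g$R / 2 + 5)
  ids <- g$cornea_ids
  r <- g$sites$r[ids]
  sel <- r >= band[1] & r < band[2] & !is.na(state$clone[ids])
  if (sum(sel) < min_labeled) return(NA_real_)
  ids <- ids[sel]
  ann <- floor(g$sites$r[ids])
  vals <- vapply(split(ids, ann), function(ii) {
    if (length(ii) < 2) return(NA_real_)
    unmixing_annulus(state$clone[ii], g$sites$theta[ii])
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Radial profile of clonal unmixing
#'
#' [unmixing()] evaluated in radial bins of width `bin_width` cells, indexed
#' by distance from the limbus.
#'
#' @param state a `tissue_state`.
#' @param bin_width radial bin width in cells (default 5, matching the local
#'   interaction radius).
#' @param min_labeled per-bin minimum labeled-site count (below: `NA`).
#' @return A data.frame of class `radial_profile` with columns `depth_lo`,
#'   `depth_hi` (distance from the limbus), `value`, `n` (labeled sites).
#' @export
unmixing_profile <- function(state, bin_width = 5, min_labeled = 8) {
  g <- state$grid
  edges <- seq(0, ceiling(g$R / bin_width) * bin_width, by = bin_width)
  out <- data.frame(depth_lo = utils::head(edges, -1),
                    depth_hi = utils::tail(edges, -1))
  out$value <- NA_real_
  out$n <- 0L
  ids <- g$cornea_ids
  r <- g$sites$r[ids]
  labeled <- !is.na(state$clone[ids])
  for (i in seq_len(nrow(out))) {
    band <- c(g$R - out$depth_hi[i], g$R - out$depth_lo[i])
    out$n[i] <- sum(labeled & r >= band[1] & r < band[2])
    out$value[i] <- unmixing(state, band = band, min_labeled = min_labeled)
  }
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Radial profile of post-mitotic cells
#'
#' Fraction of corneal cells that have exhausted their replicative lifespan
#' (`divisions >= rls`), in radial bins of distance from the limbus.
#'
#' @param state a `tissue_state`.
#' @param config a [model_config()] supplying `rls` (or pass `rls` directly).
#' @param rls replicative lifespan; overrides `config`.
#' @param bin_width radial bin width in cells.
#' @return A `radial_profile` data.frame (`depth_lo`, `depth_hi`, `value`,
#'   `n` = cells in bin). Identically 0 when `rls` exceeds every lineage
#'   depth present.
#' @export
post_mitotic_profile <- function(state, config = NULL, rls = config$rls,
                                 bin_width = 5) {
  if (is.null(rls)) stop("supply config or rls", call. = FALSE)
  g <- state$grid
  ids <- g$cornea_ids
  depth <- g$R - g$sites$r[ids]
  pm <- state$divisions[ids] >= rls
  edges <- seq(0, ceiling(g$R / bin_width) * bin_width, by = bin_width)
  bin <- cut(depth, edges, right = FALSE, include.lowest = TRUE)
  out <- data.frame(depth_lo = utils::head(edges, -1),
                    depth_hi = utils::tail(edges, -1),
                    value = as.numeric(tapply(pm, bin, mean)),
                    n = as.integer(tapply(pm, bin, length)))
  out$n[is.na(out$n)] <- 0L
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Number of distinct clones over time
#'
#' @param trajectory a `trajectory`.
#' @param region `"limbus"` or `"cornea"`.
#' @return A data.frame with `tnorm` and `count`.
#' @export
clone_counts <- function(trajectory, region = c("limbus", "cornea")) {
  region <- match.arg(region)
  col <- if (region == "limbus") "n_clones_limbus" else "n_clones_cornea"
  data.frame(tnorm = trajectory$checkpoints$tnorm,
             count = trajectory$checkpoints[[col]])
}

#' Clone-size distributions and their scale invariance
#'
#' Per checkpoint, the sizes of all clones present in `region` and their
#' rescaling by the mean (`n / <n>`). Neutral-drift clonal competition
#' predicts the rescaled distribution to be time-invariant; the two-sample
#' Kolmogorov-Smirnov distance between the last two checkpoints quantifies
#' this.
#'
#' @param trajectory a `trajectory` run with `record_snapshots = TRUE`.
#' @param region `"limbus"` or `"cornea"`.
#' @return A list with `summary` (data.frame: `tnorm`, `n_clones`,
#'   `mean_size`), `scaled` (list of `n/<n>` vectors per checkpoint), and
#'   `ks_distance` between the final two checkpoints (`NA` with fewer than
#'   two usable checkpoints).
#' @export
clone_size_stats <- function(trajectory, region = c("limbus", "cornea")) {
  region <- match.arg(region)
  if (is.null(trajectory$snapshots))
    stop("trajectory must be run with record_snapshots = TRUE", call. = FALSE)
  g <- trajectory$state$grid
  ids <- if (region == "limbus") g$limbus_ids else g$cornea_ids
  scaled <- lapply(trajectory$snapshots, function(cl) {
    sz <- as.numeric(table(cl[ids]))
    if (!length(sz)) return(numeric(0))
    sz / mean(sz)
  })
  summary <- data.frame(
    tnorm = trajectory$checkpoints$tnorm,
    n_clones = vapply(scaled, length, integer(1)),
    mean_size = vapply(trajectory$snapshots, function(cl) {
      sz <- as.numeric(table(cl[ids]))
      if (!length(sz)) NA_real_ else mean(sz)
    }, numeric(1)))
  ks <- NA_real_
  usable <- which(summary$n_clones >= 2)
  if (length(usable) >= 2) {
    i <- usable[length(usable) - 1]; j <- usable[length(usable)]
    ks <- suppressWarnings(
      stats::ks.test(scaled[[i]], scaled[[j]])$statistic)
    ks <- unname(ks)
  }
  list(summary = summary, scaled = scaled, ks_distance = ks)
}

#' Time-averaged clone-occupancy map
#'
#' Per-site distribution of clone labels over the checkpoints inside a
#' trailing window of normalized time, with the modal label per site (the
#' quantity rendered in time-average figures).
#'
#' @param trajectory a `trajectory` run with `record_snapshots = TRUE`.
#' @param window trailing window length in normalized replication times.
#' @return A list with `modal` (integer vector, per-site modal clone label,
#'   `NA` where unlabeled is modal), `modal_freq` (fraction of window
#'   checkpoints showing the modal label), and `n_checkpoints`.
#' @export
time_average_map <- function(trajectory, window) {
  if (is.null(trajectory$snapshots))
    stop("trajectory must be run with record_snapshots = TRUE", call. = FALSE)
  tn <- trajectory$checkpoints$tnorm
  span <- tn[length(tn)] - tn[1]
  if (window > span + 1e-9)
    stop("window longer than the trajectory (", signif(span, 4),
         " replication times)", call. = FALSE)
  keep <- which(tn >= tn[length(tn)] - window)
  snaps <- trajectory$snapshots[keep]
  mat <- do.call(cbind, snaps)
  modal <- integer(nrow(mat))
  freq <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    v[is.na(v)] <- 0L  # 0 stands for "unlabeled"
    tab <- tabulate(v + 1L)
    k <- which.max(tab)
    modal[i] <- k - 1L
    freq[i] <- tab[k] / length(v)
  }
  modal[modal == 0L] <- NA_integer_
  list(modal = modal, modal_freq = freq, n_checkpoints = length(keep))
}

#' Minimal replicative lifespan permitting full renewal
#'
#' Bisection search over integer RLS values: an RLS "renews" when at least
#' `votes` of the seeded runs reach 100% labeled cornea (majority vote tames
#' stochastic boundary cases). The supplied range must bracket the
#' transition.
#'
#' @param config a [model_config()]; its `rls` field is overridden.
#' @param rls_range integer vector `c(lo, hi)`: `lo` must fail, `hi` must
#'   renew.
#' @param seeds seeds for the replicate runs at each candidate RLS.
#' @param votes minimum number of renewing seeds to call an RLS feasible.
#' @param max_tnorm per-run time budget in normalized replication times.
#' @param stall_window forwarded to [run_simulation()].
#' @return The smallest feasible RLS in the range (integer).
#' @export
find_min_rls <- function(config, rls_range, seeds = 1:3, votes = 2,
                         max_tnorm = 400, stall_window = 20) {
  stopifnot(length(rls_range) == 2, rls_range[1] < rls_range[2])
  renews <- function(rls) {
    cfg <- config
    cfg$rls <- rls
    ok <- vapply(seeds, function(s) {
      tr <- run_simulation(cfg, seed = s, max_tnorm = max_tnorm,
                           stall_window = stall_window,
                           checkpoint_dt = max(1, max_tnorm / 100))
      identical(tr$stop_reason, "renewed")
    }, logical(1))
    sum(ok) >= votes
  }
  lo <- as.integer(rls_range[1]); hi <- as.integer(rls_range[2])
  if (renews(lo))
    stop("rls_range does not bracket the transition: RLS = ", lo,
         " already renews", call. = FALSE)
  if (!renews(hi))
    stop("rls_range does not bracket the transition: RLS = ", hi,
         " does not renew", call. = FALSE)
  while (hi - lo > 1L) {
    mid <- as.integer(floor((lo + hi) / 2))
    if (renews(mid)) hi <- mid else lo <- mid
  }
  hi
}
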
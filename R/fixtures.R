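#' Deterministic synthetic clone patterns
#'
#' Builds labeled tissue states with analytically known statistics, so the
#' pattern observables can be tested without running long simulations:
#'
#' * `"stripes"` — each clone occupies one contiguous angular wedge over all
#'   radii (perfect centripetal stripes; unmixing 1 in every bin).
#' * `"patches"` — contiguous connected blobs grown by seeded breadth-first
#'   region growth from random corneal seeds.
#' * `"salt_pepper"` — labels assigned independently per site (fully mixed).
#' * `"annulus_front"` — wedge labels only within `depth` cells of the
#'   limbus; deeper sites unlabeled (a renewal front of known depth).
#'
#' Limbal sites are always labeled by wedge so lineage bookkeeping stays
#' consistent; all corneal cells are progenitors with zero divisions.
#'
#' @param grid a [build_tissue()] grid.
#' @param kind one of `"stripes"`, `"patches"`, `"salt_pepper"`,
#'   `"annulus_front"`.
#' @param n_clones number of clone labels (`>= 1`, at most the corneal site
#'   count).
#' @param depth front depth in cells (annulus_front only; `<= R`).
#' @param seed integer seed (patches and salt_pepper are random given the
#'   seed; regeneration is deterministic).
#' @return A `tissue_state` at `t = 0`.
#' @examples
#' g <- build_tissue(12)
#' st <- make_pattern(g, "stripes", n_clones = 6)
#' unmixing(st, band = c(2, 10))
#' @export
make_pattern <- function(grid, kind = c("stripes", "patches", "salt_pepper",
                                        "annulus_front"),
                         n_clones = 8, depth = NULL, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "tissue_grid"))
  if (n_clones < 1 || n_clones > length(grid$cornea_ids))
    stop("n_clones must lie in [1, number of corneal sites]", call. = FALSE)

  n <- nrow(grid$sites)
  type <- ifelse(grid$sites$region == "LIMBUS", "S", "PC")
  clone <- rep(NA_integer_, n)
  divisions <- rep(0L, n)
  wedge <- function(ids) {
    as.integer(1 + pmin(floor(grid$sites$theta[ids] / (2 * pi / n_clones)),
                        n_clones - 1))
  }
  clone[grid$limbus_ids] <- wedge(grid$limbus_ids)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  cid <- grid$cornea_ids
  if (kind == "stripes") {
    clone[cid] <- wedge(cid)
  } else if (kind == "salt_pepper") {
    clone[cid] <- sample.int(n_clones, length(cid), replace = TRUE)
  } else if (kind == "annulus_front") {
    if (is.null(depth)) stop("annulus_front requires depth", call. = FALSE)
    if (depth > grid$R) stop("depth must be <= R", call. = FALSE)
    sel <- cid[grid$R - grid$sites$r[cid] < depth]
    clone[sel] <- wedge(sel)
  } else {  # patches: multi-source randomized BFS keeps every patch connected
    seeds <- sample(cid, n_clones)
    clone[seeds] <- seq_len(n_clones)
    frontier <- seeds
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in sample(frontier)) {
        for (j in grid$adjacency[[i]]) {
          if (grid$sites$region[j] == "CORNEA" && is.na(clone[j])) {
            clone[j] <- clone[i]
            nxt <- c(nxt, j)
          }
        }
      }
      frontier <- nxt
    }
  }

  structure(
    list(grid = grid, type = type, clone = clone, divisions = divisions,
         t = 0, event_count = 0),
    class = "tissue_state")
}
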
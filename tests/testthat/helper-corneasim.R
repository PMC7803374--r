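# Shared fixtures: small grids and a state builder used across test files.

grid30 <- build_tissue(31)   # cornea R = 30
grid12 <- build_tissue(13)   # cornea R = 12
grid6 <- tiny_grid(6)        # cornea R = 5

# a tissue_state with prescribed corneal clone labels on a grid
state_with_labels <- function(grid, clone = rep(NA_integer_, nrow(grid$sites)),
                              divisions = rep(0L, nrow(grid$sites))) {
  structure(
    list(grid = grid,
         type = ifelse(grid$sites$region == "LIMBUS", "S", "PC"),
         clone = as.integer(clone),
         divisions = as.integer(divisions),
         t = 0, event_count = 0),
    class = "tissue_state")
}

# brute-force lattice point count for a disk of radius r
brute_disk_count <- function(r) {
  n <- floor(r)
  sum(outer((-n:n)^2, (-n:n)^2, "+") <= r^2 + 1e-9)
}
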
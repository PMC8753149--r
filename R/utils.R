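#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## All randomness runs through withr::with_seed so no generator state leaks
## into (or depends on) the caller's session.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## Derive a stage/replicate seed from a master seed; kept < 2^31 - 1.
derive_seed <- function(master, k) {
  (as.integer(master) %% 2147483647L + 104729L * (as.integer(k) %% 20123L)) %% 2147483647L
}

## 8- and 4-neighbourhood offsets as (drow, dcol) pairs.
neighbor_offsets <- function(connectivity = 8) {
  if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

## Neighbour cell indices of `idx` (column-major) on an nr x nc grid.
cell_neighbors <- function(idx, nr, nc, connectivity = 8) {
  off <- neighbor_offsets(connectivity)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  rr <- r + off[, "dr"]
  cc <- c + off[, "dc"]
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  (cc[ok] - 1L) * nr + rr[ok]
}
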
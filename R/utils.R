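# Seeding discipline: one root seed, named substreams per stage so each
# stage (cohort assignment, lesion placement, noise, views, training) is
# independently reproducible.

#' Derive a named substream seed from a root seed
#'
#' @param seed integer root seed.
#' @param name character substream name (e.g. "lesion", "noise", "view").
#' @return An integer seed below 2^31, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 1000003 * 1009 + h) %% 2147483629)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a volume by whole voxels, padding with zeros
#'
#' @param vol 3D numeric array.
#' @param dx,dy,dz integer shifts along each axis.
#' @return Shifted array of the same dimensions.
#' @export
shift_volume <- function(vol, dx = 0L, dy = 0L, dz = 0L) {
  d <- dim(vol)
  out <- array(0, dim = d)
  src <- function(n, s) {
    from <- max(1L, 1L - s):min(n, n - s)
    list(src = from, dst = from + s)
  }
  a <- src(d[1], as.integer(dx)); b <- src(d[2], as.integer(dy)); cc <- src(d[3], as.integer(dz))
  if (length(a$src) && length(b$src) && length(cc$src))
    out[a$dst, b$dst, cc$dst] <- vol[a$src, b$src, cc$src]
  out
}

# max-pool a binary 3D mask down to target dims (used to carry lobe masks
# onto the encoder's reduced feature grid)
downsample_mask <- function(mask, target_dim) {
  d <- dim(mask)
  stopifnot(length(target_dim) == 3)
  f <- d %/% target_dim
  stopifnot(all(f >= 1), all(d == target_dim * f))
  out <- array(0, dim = target_dim)
  for (k in seq_len(target_dim[3])) for (j in seq_len(target_dim[2])) for (i in seq_len(target_dim[1])) {
    blk <- mask[((i - 1) * f[1] + 1):(i * f[1]),
                ((j - 1) * f[2] + 1):(j * f[2]),
                ((k - 1) * f[3] + 1):(k * f[3])]
    out[i, j, k] <- max(blk)
  }
  out
}
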
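# Independent straight-line reference implementations, written from the
# algorithm definitions before the package internals.  They share no code
# with the package: border replication is index clamping, dispersion is a
# plain accumulation loop, and every pixel/direction is enumerated.

oracle_dirs <- matrix(c(-1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1),
                      ncol = 2, byrow = TRUE)

oracle_dispersion <- function(v) {
  n <- length(v)
  s <- 0
  for (x in v) s <- s + x
  m <- s / n
  if (m == 0) return(0)
  ssd <- 0
  for (x in v) ssd <- ssd + (x - m) * (x - m)
  (ssd / (n * m)) * 100
}

# R-LBP by per-pixel, per-direction enumeration with clamped (replicate)
# indexing; zero_border = TRUE instead zeroes pixels whose rays leave the
# image
oracle_rlbp <- function(img, threshold = 0.15, L = 2, zero_policy = 1,
                        zero_border = FALSE) {
  h <- nrow(img); w <- ncol(img); need <- L + 1
  at <- function(r, c) img[min(max(r, 1), h), min(max(c, 1), w)]
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (zero_border &&
          (i - need < 1 || i + need > h || j - need < 1 || j + need > w)) {
        out[i, j] <- 0L
        next
      }
      code <- 0L
      for (d in 1:8) {
        ray <- numeric(need)
        for (k in 1:need)
          ray[k] <- at(i + k * oracle_dirs[d, 1], j + k * oracle_dirs[d, 2])
        cva <- oracle_dispersion(ray)
        cvb <- oracle_dispersion(c(img[i, j], ray))
        bit <- if (cva > 0) {
          if (abs(cva - cvb) / cva > threshold) 1L else 0L
        } else if (cvb > 0) as.integer(zero_policy) else 0L
        code <- code + bit * as.integer(2^(8 - d))
      }
      out[i, j] <- code
    }
  }
  out
}

oracle_lbp <- function(img) {
  h <- nrow(img); w <- ncol(img)
  at <- function(r, c) img[min(max(r, 1), h), min(max(c, 1), w)]
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      code <- 0L
      for (d in 1:8) {
        if (at(i + oracle_dirs[d, 1], j + oracle_dirs[d, 2]) >= img[i, j])
          code <- code + as.integer(2^(8 - d))
      }
      out[i, j] <- code
    }
  }
  out
}

rand_img <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# clockwise 90-degree rotation of a matrix
rot90_cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# cyclically rotate the 8-bit direction pattern of each code by `shift`
# positions (new direction d takes the bit of old direction d - shift)
rotate_code_bits <- function(codes, shift) {
  f <- function(code) {
    b <- as.integer(intToBits(code))[8:1]     # b[d] = bit of direction d
    nb <- b[((seq_len(8) - 1 - shift) %% 8) + 1]
    sum(nb * 2^(8 - seq_len(8)))
  }
  matrix(vapply(as.vector(codes), f, numeric(1)), nrow(codes), ncol(codes))
}

# cheap content digest for comparing large arrays within a test run
digest_image <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}
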
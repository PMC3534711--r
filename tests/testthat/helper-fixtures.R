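# shared fixtures built in code; all randomness goes through fixed seeds

# linear O2 profile: 250 uM at the interface to 0 at `opd` mm
o2_spec <- function(opd = 6.7, noise_sd = 0, porosity = 0.65) {
  profile_spec("O2", data.frame(depth_mm = c(0, opd), value = c(250, 0)),
               porosity = porosity, noise_sd = noise_sd)
}

# sulfide profile with an interior maximum at `peak_mm`
peak_profile <- function(peak_mm = 30, peak_uM = 800, bottom_mm = 60,
                         bottom_uM = 200, porosity = 0.95) {
  concentration_profile(seq(0, bottom_mm, by = 2),
                        approx(c(0, peak_mm, bottom_mm), c(0, peak_uM, bottom_uM),
                               xout = seq(0, bottom_mm, by = 2))$y,
                        "totalS", porosity = porosity)
}

# brute-force steepest-gradient oracle: least squares over every window
brute_gradient <- function(profile, window_pts, direction = "both") {
  sub <- profile$depth_mm >= 0
  z <- profile$depth_mm[sub]; v <- profile$value[sub]
  n <- length(z)
  best <- NULL
  for (i in seq_len(n - window_pts + 1)) {
    idx <- i:(i + window_pts - 1)
    s <- unname(coef(lm(v[idx] ~ z[idx]))[2])
    if (direction == "up" && s <= 0) next
    if (direction == "down" && s >= 0) next
    if (is.null(best) || abs(s) > abs(best)) best <- s
  }
  if (is.null(best)) 0 else best
}

# small two-group point cloud with controllable separation
two_groups <- function(n_per = 5, sep = 0, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), n_per),
             matrix(rnorm(n_per * 2, mean = sep), n_per))
  list(d = dist(x), groups = rep(c("a", "b"), each = n_per))
}

# tiny tag table with known sharing structure; equal column sums
tiny_tag_table <- function() {
  m <- matrix(c(
    5L, 5L, 5L,   # OTU1 shared by all
    4L, 4L, 0L,   # OTU2 in samples 1+2
    1L, 0L, 0L,   # OTU3 unique to 1
    0L, 1L, 0L,   # OTU4 unique to 2
    0L, 0L, 5L),  # OTU5 unique to 3
    ncol = 3, byrow = TRUE,
    dimnames = list(paste0("OTU", 1:5), c("s1", "s2", "s3")))
  tag_table(m)
}
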
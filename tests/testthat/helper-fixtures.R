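# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

CODES <- class_codes()

# a blank background grid
blank_grid <- function(n = 32L) matrix(CODES[["background"]], n, n)

# section from a raw label grid
make_section <- function(labels, pixel_size_nm = 20, section_index = 0L,
                         excluded = FALSE) {
  segmented_section(labels, pixel_size_nm = pixel_size_nm,
                    section_index = section_index, excluded = excluded)
}

# a filled disk of one class on background
disk_section <- function(diameter_um, pixel_size_nm,
                         class = "basement_membrane", margin_px = 10L) {
  r_px <- diameter_um * 1000 / 2 / pixel_size_nm
  n <- 2L * ceiling(r_px) + 2L * margin_px
  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  lab <- matrix(CODES[["background"]], n, n)
  lab[(xs - ctr)^2 + (ys - ctr)^2 <= r_px^2] <- CODES[[class]]
  make_section(lab, pixel_size_nm = pixel_size_nm)
}

# random valid label grid (all six classes)
random_grid <- function(n = 32L) {
  matrix(sample(unname(CODES), n * n, replace = TRUE), n, n)
}

# brute-force Euclidean distance transform oracle: for every foreground
# pixel, the minimum centre-to-centre distance to any background pixel
brute_force_edt <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(bg) == 0L || nrow(fg) == 0L) return(out)
  for (k in seq_len(nrow(fg))) {
    out[fg[k, 1L], fg[k, 2L]] <-
      sqrt(min((bg[, 1L] - fg[k, 1L])^2 + (bg[, 2L] - fg[k, 2L])^2))
  }
  out
}

# all permutations of 1..n as a matrix (n! rows)
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# p-value of the internal D'Agostino-Pearson omnibus test
dagostino_pearson_p <- function(x) {
  pericytemorph:::dagostino_pearson(x)$p.value
}

# hand rank-formula Kruskal-Wallis H (tie-corrected), independent of
# stats::kruskal.test
hand_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
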
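# Builders for small deterministic fixtures; all data is generated in code.

const_matrix <- function(value) matrix(value, 8L, 8L)

# 8x8 matrix with one value per hemisphere (rows 1-4 inferior)
hemi_matrix <- function(inferior, superior) {
  m <- matrix(superior, 8L, 8L)
  m[1:4, ] <- inferior
  m
}

make_eye <- function(subject, layer_values, laterality = "right") {
  grids <- lapply(names(layer_values), function(l) {
    thickness_grid(subject, l, laterality, layer_values[[l]])
  })
  names(grids) <- names(layer_values)
  eye_record(subject, laterality, grids)
}

# n-eye cohort: per-hemisphere means plus iid N(0, sd) cell noise
noisy_cohort <- function(n, layer = "RETINA", inf = 50, sup = 50, sd = 3,
                         seed = 1, laterality = "right") {
  set.seed(seed)
  eyes <- lapply(seq_len(n), function(i) {
    m <- pmax(hemi_matrix(inf, sup) + matrix(rnorm(64, 0, sd), 8L, 8L), 0)
    make_eye(sprintf("S%03d", i), stats::setNames(list(m), layer), laterality)
  })
  cohort(eyes, provenance = "test fixture")
}

# cohort whose per-pair differences are drawn from N(mu, sigma) exactly
diff_cohort <- function(n, mu, sigma, layer = "GCL", base = 50, seed = 1) {
  set.seed(seed)
  eyes <- lapply(seq_len(n), function(i) {
    m <- const_matrix(base)
    m[1:4, ] <- base + matrix(rnorm(32, mu, sigma), 4L, 8L)
    make_eye(sprintf("S%03d", i), stats::setNames(list(pmax(m, 0)), layer))
  })
  cohort(eyes, provenance = "difference fixture")
}
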
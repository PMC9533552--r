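# Small geometries and records shared across tests.

tiling_mask <- function() make_layer_geometry(60, 10, rep(10, 6))

small_geometry <- function() make_layer_geometry(70, 60, c(10, 10, 12, 10, 8, 14))

flat_slice <- function(p_red = 0.2, p_green = 0.5, rho = 1) {
  tibble::tibble(layer = retinal_layers(), p_red = p_red,
                 p_green = p_green, rho = rho)
}

# A minimal valid record with hand-made channels.
toy_record <- function(cohort = "IBA-1", mask = tiling_mask(),
                       excluded = character()) {
  ch <- function(hi) {
    m <- matrix(1000L, nrow(mask), ncol(mask))
    m[mask == 2L] <- hi  # GCL band bright
    m
  }
  roles <- if (cohort == "GS") c("gs", "gfap") else c("amyloid", "marker")
  channels <- stats::setNames(
    list(ch(30000L), ch(25000L), matrix(500L, nrow(mask), ncol(mask))),
    c(roles, "nuclei"))
  image_record(donor = "D1", group = "AD", region = "central",
               cohort = cohort, section = 1, image = 1,
               mask = mask, channels = channels, excluded = excluded)
}

# Tiny scenario for fast end-to-end runs.
tiny_scenario <- function(cohort = "IBA-1", n_ad = 2, n_control = 3,
                          seed = 7, donor_sd = 0.1) {
  default_scenario(cohort, n_ad = n_ad, n_control = n_control,
                   n_sections = 1, n_images = 1,
                   geometry = small_geometry(), donor_sd = donor_sd,
                   seed = seed)
}

# Independent brute-force oracles for the Wilcoxon machinery. These
# enumerate assignments/sign patterns directly (bitmask loops), kept
# deliberately separate from the package's combn/convolution code paths.
oracle_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  mu <- length(x) * (n + 1) / 2
  hits <- 0L; total <- 0L
  for (bits in 0:(2^n - 1)) {
    idx <- which(bitwAnd(bits, 2^(0:(n - 1))) > 0)
    if (length(idx) != length(x)) next
    total <- total + 1L
    if (abs(sum(r[idx]) - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  hits <- 0L
  for (bits in 0:(2^n - 1)) {
    pos <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    if (abs(sum(r[pos]) - mu) >= abs(v_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}
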
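# Shared fixtures and independent oracles.

# Exhaustive enumeration of every continuous path that stays inside the
# band; returns the maximal total fitness.  Independent of the DP engine:
# paths are expanded row by row as explicit (y, total) states.
enumerate_best_total <- function(values, ya, yp) {
  W <- nrow(values)
  nz <- ncol(values)
  ya <- pmax(rep_len(ya, nz), 1L)
  yp <- pmin(rep_len(yp, nz), W)
  ys <- seq.int(ya[1], yp[1])
  tot <- values[cbind(ys, 1L)]
  if (nz > 1) for (t in 2:nz) {
    y2 <- c(ys - 1L, ys, ys + 1L)
    t2 <- c(tot, tot, tot)
    keep <- y2 >= ya[t] & y2 <= yp[t]
    ys <- y2[keep]
    tot <- t2[keep] + values[cbind(ys, t)]
  }
  max(tot)
}

# Small gray image with constant background and optional vertical stripes.
# stripes: list of list(cols, value)
stripe_image <- function(W = 20, H = 20, bg = 40, stripes = list()) {
  m <- matrix(bg, W, H)
  for (s in stripes) m[s$cols, ] <- s$value
  gray_image(m)
}

# Class map built by gray-level thresholds, independent of the EM module.
threshold_cmap <- function(img, iso = c(60, 100), air_below = 15) {
  I <- img$pixels
  cls <- matrix("hypo", nrow(I), ncol(I))
  cls[I < air_below] <- "air"
  cls[I >= iso[1] & I <= iso[2]] <- "iso"
  cls[I > iso[2]] <- "hyper"
  cls
}

# Minimal synthetic gmm_fit for threshold-repair tests.
make_fit <- function(means, sds, weights, iso_lower, iso_upper) {
  labels <- c("air", "hypo", "iso", "hyper")[seq_along(means)]
  comps <- lapply(seq_along(means), function(i)
    list(mean = means[i], variance = sds[i]^2, weight = weights[i],
         label = labels[i]))
  g <- 0:255
  cls <- character(256)
  cls[g < iso_lower] <- "hypo"
  cls[g <= means[1]] <- "air"
  cls[g >= iso_lower & g <= iso_upper] <- "iso"
  cls[g > iso_upper] <- "hyper"
  structure(list(components = comps, class_of_gray = cls,
                 iso_lower = as.integer(iso_lower),
                 iso_upper = as.integer(iso_upper),
                 adjusted = FALSE, adjust_reason = "none"),
            class = "gmm_fit")
}

# Memoized phantom fixtures so several test files can share one generation.
.phantom_cache <- new.env(parent = emptyenv())
phantom_fixture <- function(seed = 1, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "|")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(seed = seed, ...))
  .phantom_cache[[key]]
}

# Run the classification + structure chain once per cached phantom slice.
.chain_cache <- new.env(parent = emptyenv())
structure_fixture <- function(seed = 1, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "|")
  if (is.null(.chain_cache[[key]])) {
    ph <- phantom_fixture(seed, ...)
    img <- ph$series$slices[[ceiling(ph$truth$k_msp)]]
    fit <- repair_iso_upper(classify_gray_levels(fit_histogram_gmm(img)))
    st <- detect_structures(img, fit)
    .chain_cache[[key]] <- list(ph = ph, img = img, fit = fit, st = st)
  }
  .chain_cache[[key]]
}
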
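# Gaussian-mixture classification of the gray-level histogram.
#
# The spinal cord serves as the intensity reference on T2-weighted images:
# pixels are classified hyper-, iso- or hypointense relative to it, with a
# fourth, very hypointense "air" class for pixels outside the body.  A
# mixture of up to four Gaussians is fitted to the 256-bin histogram with
# EM, growing the model one component at a time.

EM_TOL <- 1e-6       # relative log-likelihood convergence
EM_MAX_ITER <- 500L
EM_WEIGHT_FLOOR <- 1e-4   # components below this mixing weight collapse
EM_VAR_FLOOR <- 4         # variance floor (sd 2): gray levels are quantized
                          # integers, so tighter components are meaningless
                          # and would collapse onto single-bin spikes

TISSUE_CLASSES <- c("air", "hypo", "iso", "hyper")

# Weighted EM on a 256-bin histogram for a fixed number of components.
# Returns list(components, loglik_trace, converged).
em_fit_k <- function(counts, comps) {
  g <- 0:255
  N <- sum(counts)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(EM_MAX_ITER)) {
    # E-step in log space to avoid underflow at extreme gray levels
    logdens <- vapply(comps, function(cp)
      log(cp$weight) + stats::dnorm(g, cp$mean, sqrt(cp$variance), log = TRUE),
      numeric(256))
    mx <- apply(logdens, 1, max)
    dens <- exp(logdens - mx)
    tot <- rowSums(dens)
    resp <- dens / tot
    ll <- sum(counts * (log(tot) + mx))
    ll_trace <- c(ll_trace, ll)
    # M-step
    for (i in seq_along(comps)) {
      wn <- counts * resp[, i]
      wsum <- sum(wn)
      comps[[i]]$weight <- wsum / N
      if (wsum > 0) {
        mu <- sum(wn * g) / wsum
        comps[[i]]$mean <- mu
        comps[[i]]$variance <- max(sum(wn * (g - mu)^2) / wsum, EM_VAR_FLOOR)
      }
    }
    # collapse vanishing components and renormalise
    w <- vapply(comps, `[[`, numeric(1), "weight")
    if (any(w < EM_WEIGHT_FLOOR) && length(comps) > 1) {
      comps <- comps[w >= EM_WEIGHT_FLOOR]
      w <- vapply(comps, `[[`, numeric(1), "weight")
    }
    for (i in seq_along(comps)) comps[[i]]$weight <- w[i] / sum(w)
    if (is.finite(ll_old) && abs(ll - ll_old) < EM_TOL * abs(ll_old)) {
      return(list(components = comps, loglik = ll_trace, converged = TRUE))
    }
    ll_old <- ll
  }
  list(components = comps, loglik = ll_trace, converged = FALSE)
}

#' Fit a Gaussian mixture to a slice's gray-level histogram
#'
#' EM is run for component counts 1, 2, 3, 4.  Each stage is initialised
#' from the previous converged fit by adding one component at the gray
#' level where the model underestimates the histogram the most (the
#' residual peak), which reliably discovers the air, soft-tissue, cord and
#' CSF peaks one by one.  The initialisation is fully deterministic; `seed`
#' is accepted for interface stability and recorded in the fit.  Components
#' are relabeled by ascending mean as air, hypo, iso, hyper (fewer labels
#' when components collapse).
#'
#' @param img a [gray_image()].
#' @param seed integer, recorded in the fit.
#' @return An object of class `gmm_fit` with `components` (each a list with
#'   `mean`, `variance`, `weight`, `label`), per-stage `loglik` traces and
#'   the histogram used.
#' @export
fit_histogram_gmm <- function(img, seed = 1L) {
  counts <- tabulate(as.integer(img$pixels) + 1L, nbins = 256)
  nz <- which(counts > 0) - 1L
  if (length(nz) == 1L) {
    warning("degenerate single-valued image; returning one component")
    comps <- list(list(weight = 1, mean = nz, variance = EM_VAR_FLOOR))
    fit <- list(components = comps, loglik = list(numeric(0)),
                counts = counts, seed = seed)
    return(label_components(fit))
  }
  g <- 0:255
  mu0 <- sum(counts * g) / sum(counts)
  v0 <- max(sum(counts * (g - mu0)^2) / sum(counts), EM_VAR_FLOOR)
  comps <- list(list(weight = 1, mean = mu0, variance = v0))
  traces <- list()
  emp <- counts / sum(counts)
  for (ncomp in 1:4) {
    if (ncomp == 1) {
      res <- em_fit_k(counts, comps)
    } else {
      # greedy growth: propose the new component at the residual peaks
      # (mutually >= 16 gray levels apart and away from existing means),
      # run EM from each proposal, keep the best converged likelihood
      model <- rowSums(vapply(comps, function(cp)
        cp$weight * stats::dnorm(g, cp$mean, sqrt(cp$variance)), numeric(256)))
      resid <- emp - model
      mus <- vapply(comps, `[[`, numeric(1), "mean")
      cands <- numeric(0)
      for (gi in g[order(resid, decreasing = TRUE)]) {
        if (all(abs(gi - c(mus, cands)) >= 16)) cands <- c(cands, gi)
        if (length(cands) >= 4L) break
      }
      if (length(cands) == 0) cands <- g[which.max(resid)]
      base <- lapply(comps, function(cp) { cp$weight <- cp$weight * 0.9; cp })
      res <- NULL
      for (cand in cands) {
        trial <- em_fit_k(counts, c(base, list(
          list(weight = 0.1, mean = cand, variance = 25))))
        if (is.null(res) ||
            trial$loglik[length(trial$loglik)] > res$loglik[length(res$loglik)])
          res <- trial
      }
    }
    comps <- res$components
    traces[[ncomp]] <- res$loglik
  }
  fit <- list(components = comps, loglik = traces, counts = counts,
              seed = seed)
  label_components(fit)
}

# Order components by ascending mean and attach tissue-class labels.
label_components <- function(fit) {
  mus <- vapply(fit$components, `[[`, numeric(1), "mean")
  fit$components <- fit$components[order(mus)]
  labels <- TISSUE_CLASSES[seq_along(fit$components)]
  for (i in seq_along(fit$components)) fit$components[[i]]$label <- labels[i]
  class(fit) <- "gmm_fit"
  fit
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit>\n")
  for (cp in x$components)
    cat(sprintf("  %-5s mean %6.1f  sd %5.1f  weight %.3f\n",
                cp$label, cp$mean, sqrt(cp$variance), cp$weight))
  if (!is.null(x$iso_lower))
    cat(sprintf("  iso range [%d, %d]%s\n", x$iso_lower, x$iso_upper,
                if (isTRUE(x$adjusted)) paste0(" (adjusted: ", x$adjust_reason, ")")
                else ""))
  invisible(x)
}

#' Classify every gray level by its dominant mixture component
#'
#' Gray level g takes the class of the component with the largest
#' weight-times-density at g; gray levels below the air component's mean are
#' overridden to air.  The iso thresholds `iso_lower`/`iso_upper` are the
#' smallest and largest gray levels classified isointense.
#'
#' @param fit a `gmm_fit` from [fit_histogram_gmm()].
#' @return The fit with `class_of_gray` (a length-256 character vector for
#'   gray levels 0..255), `iso_lower` and `iso_upper` attached.
#' @export
classify_gray_levels <- function(fit) {
  g <- 0:255
  logdens <- vapply(fit$components, function(cp)
    log(cp$weight) + stats::dnorm(g, cp$mean, sqrt(cp$variance), log = TRUE),
    numeric(256))
  labels <- vapply(fit$components, `[[`, character(1), "label")
  cls <- labels[max.col(logdens, ties.method = "first")]
  air_mean <- fit$components[[1]]$mean
  cls[g < air_mean] <- labels[1]
  fit$class_of_gray <- cls
  iso <- which(cls == "iso") - 1L
  if (length(iso) > 0) {
    fit$iso_lower <- min(iso)
    fit$iso_upper <- max(iso)
  } else {
    warning("no gray level classified isointense")
    fit$iso_lower <- NA_integer_
    fit$iso_upper <- NA_integer_
  }
  fit$adjusted <- FALSE
  fit$adjust_reason <- "none"
  fit
}

#' Repair an out-of-range isointense upper threshold
#'
#' The cord's gray levels are expected between roughly 60 and 100, so the
#' upper isointense threshold derived from the mixture is sanity-checked:
#' a value in `[64, 128]` is kept (128 being the low-branch repair value,
#' which must count as acceptable for the repair to be idempotent); a value
#' above that is recomputed from the isointense component as mean + 2 sd
#' and clamped into `[127, 159]`; a value below 64 (the isointense
#' component swallowed by the hypointense peak) is reset to 128 without
#' recomputation.  The class map is updated so
#' that the iso/hyper boundary matches the repaired threshold.  The repair
#' is idempotent.
#'
#' @param fit a classified `gmm_fit` (see [classify_gray_levels()]).
#' @return The fit with possibly updated `iso_upper`, `class_of_gray`, and
#'   the `adjusted` flag and `adjust_reason` recording which branch fired.
#' @export
repair_iso_upper <- function(fit) {
  t0 <- fit$iso_upper
  if (is.na(t0)) {
    fit$iso_upper <- 128L
    fit$adjusted <- TRUE
    fit$adjust_reason <- "missing iso class; threshold set to 128"
    return(apply_iso_upper(fit))
  }
  # 128 counts as in range: it is the low-branch repair value itself, and
  # re-adjusting it would make the repair non-idempotent
  if (t0 >= 64 && t0 <= 128) {
    fit$adjusted <- FALSE
    fit$adjust_reason <- "none"
    return(fit)
  }
  if (t0 > 128) {
    iso <- Filter(function(cp) cp$label == "iso", fit$components)[[1]]
    fit$iso_upper <- as.integer(clamp(round(iso$mean + 2 * sqrt(iso$variance)),
                                      127, 159))
    fit$adjusted <- TRUE
    fit$adjust_reason <- "above 127; recomputed as iso mean + 2 sd"
  } else {
    fit$iso_upper <- 128L
    fit$adjusted <- TRUE
    fit$adjust_reason <- "below 64; set to 128"
  }
  apply_iso_upper(fit)
}

# Rewrite the iso/hyper boundary of the class map at the repaired threshold.
apply_iso_upper <- function(fit) {
  g <- 0:255
  cls <- fit$class_of_gray
  cls[cls %in% c("iso", "hyper")] <-
    ifelse(g[cls %in% c("iso", "hyper")] <= fit$iso_upper, "iso", "hyper")
  fit$class_of_gray <- cls
  iso <- which(cls == "iso") - 1L
  if (length(iso) > 0) fit$iso_lower <- min(iso)
  fit
}

#' Per-pixel tissue-class map of an image
#'
#' @param img a [gray_image()].
#' @param fit a classified (and typically repaired) `gmm_fit`.
#' @return character matrix `[y, z]` of classes in
#'   `c("air", "hypo", "iso", "hyper")`.
#' @export
class_map <- function(img, fit) {
  m <- matrix(fit$class_of_gray[as.integer(img$pixels) + 1L],
              img$width_y, img$height_z)
  m
}
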
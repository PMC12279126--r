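#' Cohort simulation parameters
#'
#' Parameters of the synthetic survival cohort.  Healing times follow a
#' Weibull proportional-hazards model whose linear predictor combines six
#' clinical covariates (gender, age, diabetes, lesion diameter, tooth
#' position, tooth location) with a latent boundary-sharpness term
#' `1 / transition_width`, standardized over the cohort.  Healing is only
#' observed at radiographic follow-up visits every `followup_grid` months, so
#' observed event times are rounded up to the next visit; censoring occurs at
#' `max_followup` or at a random dropout visit.
#'
#' Clinical covariate frequencies default to values typical of an endodontic
#' AP case mix (about 38 percent female, 30 percent diabetic, 65 percent
#' mandibular, anterior/premolar/molar roughly 28/28/44 percent, age about
#' 52 +/- 19 years, lesion diameter about 10 +/- 3.3 mm truncated to
#' [5, 15] mm).
#'
#' @param n_patients Number of patients.
#' @param beta_clinical Named log-hazard coefficients for
#'   `gender` (female = 1), `age` (years), `diabetes`, `lesion_mm`,
#'   `position` (mandible = 1), `loc_premolar`, `loc_molar`.
#' @param beta_boundary Log-hazard coefficient of standardized boundary
#'   sharpness (`1 / transition_width`).  Negative values make sharply
#'   demarcated lesions heal more slowly (blurred, "acute" boundaries heal
#'   fastest).
#' @param weibull_shape,weibull_scale Baseline Weibull parameters (months).
#' @param followup_grid Months between radiographs (default 3).
#' @param max_followup Administrative censoring time in months.
#' @param dropout_prob Per-visit probability of dropping out before healing.
#' @param transition_range Range (mm) of per-patient transition widths.
#' @param split_ratio Development fraction of the development:validation
#'   split (default 0.6, i.e. 6:4).
#' @param seed RNG seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 250L,
                          beta_clinical = c(gender = 0, age = -0.008,
                                            diabetes = -0.5, lesion_mm = -0.06,
                                            position = 0.15,
                                            loc_premolar = -0.1, loc_molar = -0.3),
                          beta_boundary = -1.3,
                          weibull_shape = 1.6,
                          weibull_scale = 24,
                          followup_grid = 3,
                          max_followup = 36,
                          dropout_prob = 0.015,
                          transition_range = c(0.2, 0.8),
                          split_ratio = 0.6,
                          seed = 1L) {
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    stopf("apexfa_value_error", "Weibull shape and scale must be positive")
  }
  if (followup_grid <= 0) stopf("apexfa_value_error", "followup_grid must be > 0")
  if (split_ratio <= 0 || split_ratio >= 1) {
    stopf("apexfa_value_error", "split_ratio fraction must lie in (0, 1)")
  }
  need <- c("gender", "age", "diabetes", "lesion_mm", "position",
            "loc_premolar", "loc_molar")
  if (!all(need %in% names(beta_clinical))) {
    stopf("apexfa_value_error", "beta_clinical must name: %s",
          paste(need, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients),
                 beta_clinical = beta_clinical,
                 beta_boundary = beta_boundary,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 followup_grid = followup_grid,
                 max_followup = max_followup,
                 dropout_prob = dropout_prob,
                 transition_range = transition_range,
                 split_ratio = split_ratio,
                 seed = seed),
            class = "cohort_params")
}

clinical_design <- function(tab) {
  cbind(gender = tab$gender, age = tab$age, diabetes = tab$diabetes,
        lesion_mm = tab$lesion_mm, position = tab$position,
        loc_premolar = as.numeric(tab$location == "premolar"),
        loc_molar = as.numeric(tab$location == "molar"))
}

#' Generate a synthetic cohort of radiographs and healing outcomes
#'
#' Draws clinical covariates and a per-patient boundary transition width,
#' simulates Weibull proportional-hazards healing times observed on the
#' radiographic follow-up grid, and (optionally) renders one lesion phantom
#' per patient whose transition width carries the prognostic boundary signal.
#'
#' @param cp A [cohort_params()] object.
#' @param pp A [phantom_params()] template used for the per-patient images
#'   (its diameter, transition width, and seed are overridden per patient).
#' @param images If `FALSE`, only the outcome table and ground truth are
#'   generated (fast path for statistical simulations).
#' @return A list of class `synthetic_cohort` with `table` (data.frame:
#'   patient_id, covariates, time_months, event, cohort), `images` (list of
#'   [radiograph] or NULL), and `truth` (per-patient transition width, linear
#'   predictor, latent healing time, true contour when images are drawn).
#' @export
generate_cohort <- function(cp = cohort_params(),
                            pp = phantom_params(trabecular_amplitude = 5,
                                                noise_sd = 2),
                            images = TRUE) {
  stopifnot(inherits(cp, "cohort_params"))
  n <- cp$n_patients
  with_local_seed(cp$seed, {
    tab <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      gender = stats::rbinom(n, 1, 0.38),
      age = round(pmin(pmax(stats::rnorm(n, 52, 19), 18), 90), 1),
      diabetes = stats::rbinom(n, 1, 0.30),
      lesion_mm = round(pmin(pmax(stats::rnorm(n, 10, 3.3), 5), 15), 1),
      position = stats::rbinom(n, 1, 0.65),
      location = sample(c("anterior", "premolar", "molar"), n, TRUE,
                        prob = c(0.28, 0.28, 0.44)),
      stringsAsFactors = FALSE
    )
    tw <- stats::runif(n, cp$transition_range[1], cp$transition_range[2])
    sharp <- 1 / tw
    sharp_std <- as.numeric(scale(sharp))
    Z <- clinical_design(tab)
    Zc <- sweep(Z, 2, colMeans(Z))                 # centre so the baseline is interpretable
    eta <- as.numeric(Zc %*% cp$beta_clinical[colnames(Z)]) +
      cp$beta_boundary * sharp_std
    u <- stats::runif(n)
    latent <- cp$weibull_scale * (-log(u) / exp(eta))^(1 / cp$weibull_shape)
    g <- cp$followup_grid
    cens <- if (cp$dropout_prob > 0) {
      n_drop <- stats::rgeom(n, cp$dropout_prob)   # visits attended before dropout
      pmin(cp$max_followup, (n_drop + 1L) * g)
    } else rep(cp$max_followup, n)
    seen <- g * ceiling(latent / g)                # first visit at/after healing
    event <- as.integer(seen <= cens)
    time <- ifelse(event == 1L, seen, cens)
    n_dev <- round(cp$split_ratio * n)
    dev_idx <- sample.int(n, n_dev)
    tab$time_months <- time
    tab$event <- event
    tab$cohort <- "val"
    tab$cohort[dev_idx] <- "dev"
    imgs <- NULL
    contours <- NULL
    if (images) {
      imgs <- vector("list", n)
      contours <- vector("list", n)
      for (i in seq_len(n)) {
        ppi <- pp
        ppi$lesion_diameter <- tab$lesion_mm[i]
        ppi$transition_width <- tw[i]
        ppi$seed <- derive_seed(cp$seed, i)
        # adaptive canvas: lesion + 3 mm margin each side
        side_px <- ceiling((tab$lesion_mm[i] + 6) / ppi$pixel_spacing)
        ppi$image_size <- c(side_px, side_px)
        ppi$lesion_center <- (ppi$image_size + 1) / 2
        ph <- generate_phantom(ppi)
        ph$image$id <- tab$patient_id[i]
        imgs[[i]] <- ph$image
        contours[[i]] <- ph$contour
      }
    }
  })
  structure(list(table = tab,
                 images = imgs,
                 truth = list(transition_width = tw,
                              sharpness_std = sharp_std,
                              linear_predictor = eta,
                              latent_time = latent,
                              contours = contours)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients (%d dev / %d val), %d events, %s images>\n",
              nrow(x$table), sum(x$table$cohort == "dev"),
              sum(x$table$cohort == "val"), sum(x$table$event),
              if (is.null(x$images)) "no" else length(x$images)))
  invisible(x)
}

#' Write / read a cohort outcome table as CSV
#'
#' @param cohort A `synthetic_cohort` or its `table`.
#' @param path CSV path.
#' @return `write_cohort_csv` the path invisibly; `read_cohort_csv` a
#'   data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- if (inherits(cohort, "synthetic_cohort")) cohort$table else cohort
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
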
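# Synthetic asynchronous populations with known ground truth.

#' Sample a synthetic cytometry population
#'
#' Draws `n` cells from an asynchronous population: each event receives a
#' normalized cell-cycle position `u` (uniform, or weighted by the
#' exponential-growth age density `2*ln2*2^(-u)` so that newborns are twice
#' as frequent as dividing cells), every channel is set to its programmed
#' curve value at `u` times a multiplicative log-normal noise factor with
#' the channel's CV, and any scatter-proportional background
#' (`background_slope * ssc`) is added. An optional uniform contaminant
#' cloud supports preprocessing tests. Per-event truth (`u`, phase label,
#' contaminant flag) is retained.
#'
#' @param model a [phase_model()].
#' @param n number of events (>= 1000 for the recovery guarantees).
#' @param seed integer seed; fixed seeds give reproducible populations.
#' @param age_weighted draw `u` from the exponential-growth age density
#'   (default) or uniformly.
#' @param contaminant_fraction fraction of extra events drawn uniformly over
#'   1.2x each channel's programmed range (truth-labeled as contaminants).
#' @return an object of class `synthetic_population`: list with `events`
#'   (an [event_table()]) and `truth` (data frame `u`, `phase`,
#'   `contaminant`).
#' @export
sample_population <- function(model, n, seed = NULL, age_weighted = TRUE,
                              contaminant_fraction = 0) {
  stopifnot(inherits(model, "phase_model"))
  if (!is_count(n)) stop("n must be a positive integer")
  if (n < 1000) warning("n < 1000: recovery guarantees are void at this size")
  stopifnot(contaminant_fraction >= 0, contaminant_fraction < 1)

  with_seed(seed, {
    p <- runif(n)
    u <- if (age_weighted) age_quantile(p) else p
    chans <- names(model$marker_curves)
    vals <- lapply(chans, function(ch) {
      cv <- model$noise_cv[[ch]]
      y <- model$marker_curves[[ch]](u)
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        y <- y * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      y
    })
    names(vals) <- chans
    df <- as.data.frame(vals)
    if (any(model$background_slope != 0)) {
      ssc <- df$ssc
      for (ch in chans) {
        b <- model$background_slope[[ch]]
        if (b != 0 && ch != "ssc") df[[ch]] <- df[[ch]] + b * ssc
      }
    }
    truth <- data.frame(u = u, phase = as.character(phase_of(u, model)),
                        contaminant = FALSE, stringsAsFactors = FALSE)

    n_c <- round(contaminant_fraction * n)
    if (n_c > 0) {
      hi <- vapply(df, max, numeric(1)) * 1.2
      contam <- as.data.frame(lapply(hi, function(h) runif(n_c, 0, h)))
      names(contam) <- chans
      df <- rbind(df, contam)
      truth <- rbind(truth, data.frame(u = rep(NA_real_, n_c),
                                       phase = rep("contaminant", n_c),
                                       contaminant = rep(TRUE, n_c)))
      # shuffle so contaminants are interleaved like real acquisitions
      ord <- sample.int(nrow(df))
      df <- df[ord, , drop = FALSE]
      truth <- truth[ord, , drop = FALSE]
      rownames(df) <- rownames(truth) <- NULL
    }

    structure(list(events = event_table(df, metadata = list(source = "synthetic")),
                   truth = truth),
              class = "synthetic_population")
  })
}

#' Sample independently stained replicate populations
#'
#' Real replicates are separately stained and measured samples, so they
#' carry staining error as well as sampling error. Each replicate drawn
#' here receives its own per-channel global staining scale factor
#' (log-normal, mean 1, CV `staining_cv`) applied on top of the per-event
#' measurement noise: stoichiometric DNA dyes vary little between samples,
#' antibody channels more.
#'
#' @param model a [phase_model()].
#' @param n events per replicate.
#' @param n_replicates number of replicates.
#' @param seed integer seed (replicate k uses `seed + k`).
#' @param staining_cv named per-channel between-sample CV.
#' @param ... passed to [sample_population()].
#' @return list of `synthetic_population`s; each carries its scale factors
#'   in `$staining_factors`.
#' @export
sample_replicates <- function(model, n, n_replicates = 3, seed = NULL,
                              staining_cv = c(dna = 0.01, dna_width = 0.01,
                                              cyclin_a2 = 0.05,
                                              cyclin_b1 = 0.05, phh3 = 0.05,
                                              ssc = 0.02),
                              ...) {
  stopifnot(inherits(model, "phase_model"), is_count(n_replicates))
  lapply(seq_len(n_replicates), function(k) {
    with_seed(if (is.null(seed)) NULL else seed + k, {
      pop <- sample_population(model, n, seed = NULL, ...)
      chans <- names(pop$events$data)
      cvs <- ifelse(chans %in% names(staining_cv), staining_cv[chans], 0)
      sdlog <- sqrt(log(1 + cvs^2))
      fac <- exp(rnorm(length(chans), -sdlog^2 / 2, sdlog))
      names(fac) <- chans
      for (i in seq_along(chans)) {
        pop$events$data[[chans[i]]] <- pop$events$data[[chans[i]]] * fac[i]
      }
      pop$staining_factors <- fac
      pop
    })
  })
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("synthetic_population:", nrow(x$truth), "events;",
      sum(x$truth$contaminant), "contaminants\n")
  print(x$events)
  invisible(x)
}

#' Write a synthetic population as CSV
#'
#' One row per event: the named channel columns followed by the truth
#' columns `truth_u`, `truth_phase`, `truth_contaminant`.
#'
#' @param population a [sample_population()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  stopifnot(inherits(population, "synthetic_population"))
  df <- population$events$data
  df$truth_u <- population$truth$u
  df$truth_phase <- population$truth$phase
  df$truth_contaminant <- population$truth$contaminant
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
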
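#' Run the full per-trait study pipeline
#'
#' For every trait in the trait table: apply the presence filter (traits
#' with a nonzero value in fewer than `min_frequency` percent of the
#' animals are reported as excluded), fit the linear mixed model and —
#' where the trait is a non-negative integer vector — the zero-inflated
#' Poisson model, choose between them by DIC, compute the Savage-Dickey
#' Bayes factors for the three variance ratios from the chosen model's
#' chain, and summarize posteriors and convergence.  Per-trait seeds are
#' derived from the master seed plus the trait index, so single traits
#' can be reproduced in isolation.
#'
#' @param pedigree a `pedigree` object, or a path readable by
#'   [read_pedigree()].
#' @param metadata a metadata data.frame, or a path readable by
#'   [read_metadata()].
#' @param traits a trait table (first column `animal`), or a path
#'   readable by [read_traits()].
#' @param trait_kind kind passed to the frequency filter logic; traits
#'   are assumed already integer-transformed.
#' @param control settings from [vr_control()].
#' @param seed master integer seed.
#' @param min_frequency presence threshold in percent (default 5).
#' @param traits_subset optional character vector restricting the traits.
#' @param output_dir if given, the report (TSV) and a JSON run manifest
#'   are written there.
#' @return a `vr_study` list with `report` (one row per trait) and
#'   `fits` (the `vrfit` objects, named by trait).
#' @export
vr_study <- function(pedigree, metadata, traits, trait_kind = "otu",
                     control = vr_control(), seed = 1,
                     min_frequency = 5, traits_subset = NULL,
                     output_dir = NULL) {
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(traits)) traits <- read_traits(traits)
  validate_metadata(metadata)
  trait_names <- setdiff(names(traits), "animal")
  if (!is.null(traits_subset)) trait_names <- intersect(trait_names, traits_subset)
  if (!length(trait_names)) stop("no traits to analyze")

  ids <- as.character(traits$animal)
  missing_meta <- setdiff(ids, as.character(metadata$animal))
  if (length(missing_meta))
    stop("trait-table animal(s) absent from metadata: ",
         paste(head(missing_meta, 5L), collapse = ", "))
  metadata <- metadata[match(ids, as.character(metadata$animal)), ]
  sped <- if (is_sorted_pedigree(pedigree)) pedigree else sort_pedigree(pedigree)
  missing_ped <- setdiff(ids, sped$animal)
  if (length(missing_ped))
    stop("observed animal(s) absent from pedigree: ",
         paste(head(missing_ped, 5L), collapse = ", "))
  design <- build_design(metadata)
  A <- relationship_matrix(sped)
  kernels <- make_kernels(A, design)

  fits <- list()
  rows <- vector("list", length(trait_names))
  for (k in seq_along(trait_names)) {
    nm <- trait_names[k]
    y <- traits[[nm]]
    fc <- trait_frequency_class(y)
    row <- data.frame(trait = nm, frequency = fc$frequency,
                      freq_class = fc$class, excluded = fc$excluded,
                      reason = NA_character_, model = NA_character_,
                      dic_lmm = NA_real_, dic_zip = NA_real_,
                      stringsAsFactors = FALSE)
    for (r in c("h2", "l2", "c2"))
      row[paste0(c("bf_", "evidence_", "null_supported_", "mean_", "sd_",
                   "prob_gt_", "geweke_"), r)] <-
        list(NA_real_, NA_character_, NA, NA_real_, NA_real_, NA_real_,
             NA_real_)
    row$p_mean <- NA_real_
    if (fc$excluded) {
      row$reason <- sprintf("present in fewer than %g%% of animals",
                            min_frequency)
      rows[[k]] <- row
      message("trait ", nm, ": excluded (frequency ", round(fc$frequency, 1),
              "%)")
      next
    }
    fit <- vr_fit_core(y, design$X, kernels, model = "auto",
                       control = control,
                       seed = if (is.null(seed)) NULL else seed + k,
                       trait = nm)
    fits[[nm]] <- fit
    row$model <- fit$model
    row$dic_lmm <- if (!is.null(fit$dic$lmm)) fit$dic$lmm$dic else NA_real_
    row$dic_zip <- if (!is.null(fit$dic$zip)) fit$dic$zip$dic else NA_real_
    if (!is.null(fit$zip_skipped)) row$reason <- paste("ZIP skipped:", fit$zip_skipped)
    s <- fit$summary
    for (j in seq_len(nrow(s))) {
      r <- s$parameter[j]
      row[[paste0("mean_", r)]] <- s$mean[j]
      row[[paste0("sd_", r)]] <- s$sd[j]
      row[[paste0("prob_gt_", r)]] <- s$prob_exceeds[j]
      row[[paste0("geweke_", r)]] <- s$geweke_z[j]
    }
    if (!is.null(fit$bf))
      for (j in seq_len(nrow(fit$bf))) {
        r <- fit$bf$ratio[j]
        row[[paste0("bf_", r)]] <- fit$bf$bf[j]
        row[[paste0("evidence_", r)]] <- fit$bf$evidence[j]
        row[[paste0("null_supported_", r)]] <- fit$bf$null_supported[j]
      }
    if (fit$model == "zip")
      row$p_mean <- mean(plogis(fit$chains$zip$pstar))
    rows[[k]] <- row
    message("trait ", nm, ": ", toupper(fit$model), " selected")
  }
  report <- do.call(rbind, rows)
  out <- structure(list(report = report, fits = fits,
                        settings = control, seed = seed),
                   class = "vr_study")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(report, file.path(output_dir, "report.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest <- list(package = "vrbayes",
                     version = as.character(utils::packageVersion("vrbayes")),
                     seed = seed, settings = control[
                       c("n_iter", "burnin", "grid_size", "zip_focus")],
                     n_traits = nrow(report),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' @export
print.vr_study <- function(x, ...) {
  cat("Variance-ratio study:", nrow(x$report), "trait(s)\n")
  cat("  excluded:", sum(x$report$excluded), "\n")
  tb <- table(x$report$model, useNA = "no")
  for (m in names(tb)) cat("  ", toupper(m), "selected:", tb[[m]], "\n")
  invisible(x)
}

#' Count traits per evidence class and effect
#'
#' Tabulates, for each effect (h2, l2, c2), how many analyzed traits fall
#' in each Bayes-factor evidence class, plus how many support the null
#' (`1/BF > 3.2`).
#'
#' @param report the report data.frame of a [vr_study()] result (or the
#'   `vr_study` object itself).
#' @return data.frame with one row per effect: counts of `none`,
#'   `substantial`, `strong`, `decisive` and `null_supported`.
#' @export
summarize_evidence <- function(report) {
  if (inherits(report, "vr_study")) report <- report$report
  lv <- c("none", "substantial", "strong", "decisive")
  rows <- lapply(c("h2", "l2", "c2"), function(r) {
    ev <- report[[paste0("evidence_", r)]]
    ev <- ev[!is.na(ev)]
    ns <- report[[paste0("null_supported_", r)]]
    cnt <- table(factor(ev, levels = lv))
    data.frame(effect = r, none = cnt[["none"]],
               substantial = cnt[["substantial"]], strong = cnt[["strong"]],
               decisive = cnt[["decisive"]],
               null_supported = sum(ns, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
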
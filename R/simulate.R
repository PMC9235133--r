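#' Simulate a multi-generation pedigree
#'
#' Founders (half sires, half dams) followed by `n_generations` rounds of
#' random matings: every dam of the current generation is mated to a
#' randomly drawn sire of the same generation (sires may serve several
#' dams), producing `litter_size` offspring of random sex.  Small
#' populations naturally accumulate inbreeding from generation 3 onward.
#'
#' @param n_founders even number of founders (>= 2).
#' @param n_generations number of offspring generations (0 = founders only).
#' @param litter_size offspring per mating.
#' @param n_matings matings per generation (default: all current dams).
#' @param seed optional integer seed.
#' @return a sorted `pedigree` with attributes `generation` and `sex`.
#' @export
simulate_pedigree <- function(n_founders = 20, n_generations = 3,
                              litter_size = 4, n_matings = NULL,
                              seed = NULL) {
  if (n_founders < 2 || n_founders %% 2 != 0)
    stop("n_founders must be an even number >= 2")
  with_seed(seed, {
    animal <- sprintf("F%03d", seq_len(n_founders))
    sex <- rep(c("M", "F"), length.out = n_founders)
    ped <- data.frame(animal = animal, sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    gen <- rep(0L, n_founders)
    cur <- seq_len(n_founders)
    counter <- 0L
    for (g in seq_len(n_generations)) {
      sires <- ped$animal[cur][sex[cur] == "M"]
      dams <- ped$animal[cur][sex[cur] == "F"]
      if (!length(sires) || !length(dams))
        stop("infeasible configuration: a generation lost one sex entirely")
      nm <- n_matings %||% length(dams)
      use_dams <- if (nm <= length(dams)) sample(dams, nm) else
        sample(dams, nm, replace = TRUE)
      use_sires <- sample(sires, nm, replace = TRUE)
      kids <- nm * litter_size
      ids <- sprintf("G%d_%04d", g, counter + seq_len(kids))
      counter <- counter + kids
      new <- data.frame(animal = ids,
                        sire = rep(use_sires, each = litter_size),
                        dam = rep(use_dams, each = litter_size),
                        stringsAsFactors = FALSE)
      # balanced sex ratio in expectation and realization
      sex <- c(sex, sample(rep(c("M", "F"), length.out = kids)))
      gen <- c(gen, rep(g, kids))
      cur <- nrow(ped) + seq_len(kids)
      ped <- rbind(ped, new)
    }
    out <- structure(ped, class = c("pedigree", "data.frame"),
                     row.names = seq_len(nrow(ped)))
    attr(out, "generation") <- gen
    attr(out, "sex") <- sex
    out
  })
}

#' Gene-drop breeding values down a pedigree
#'
#' Founders draw `u ~ N(0, sigma2_a)`; each non-founder draws
#' `u = 0.5 (u_sire + u_dam) + m` with Mendelian-sampling variance
#' `sigma2_a (0.5 - (F_sire + F_dam)/4)` (an unknown parent contributes
#' neither mean nor inbreeding and widens the deviation accordingly).
#' Inbreeding coefficients come from the tabular relationship matrix, so
#' over replicates `Cov(u) = A sigma2_a`: the generator doubles as a
#' Monte-Carlo oracle for the tabular method.
#'
#' @param ped sorted `pedigree`.
#' @param sigma2_a additive genetic variance.
#' @param n_rep number of independent replicate gene drops.
#' @param seed optional integer seed.
#' @return matrix of breeding values (animals x replicates); a vector if
#'   `n_rep = 1`.
#' @export
simulate_breeding_values <- function(ped, sigma2_a = 1, n_rep = 1,
                                     seed = NULL) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  if (!is_sorted_pedigree(ped)) stop("pedigree must be sorted")
  n <- nrow(ped)
  pos <- seq_len(n); names(pos) <- ped$animal
  si <- unname(pos[ped$sire]); di <- unname(pos[ped$dam])
  Fi <- diag(relationship_matrix(ped)) - 1
  with_seed(seed, {
    u <- matrix(0, n, n_rep)
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      if (is.na(s) && is.na(d)) {
        u[i, ] <- rnorm(n_rep, 0, sqrt(sigma2_a))
      } else {
        pm <- 0; vm <- 1
        if (!is.na(s)) { pm <- pm + 0.5 * u[s, ]; vm <- vm - 0.25 * (1 + Fi[s]) }
        if (!is.na(d)) { pm <- pm + 0.5 * u[d, ]; vm <- vm - 0.25 * (1 + Fi[d]) }
        u[i, ] <- pm + rnorm(n_rep, 0, sqrt(sigma2_a * vm))
      }
    }
    rownames(u) <- ped$animal
    if (n_rep == 1) u[, 1] else u
  })
}

#' Assign litters, cages and systematic factors to the final generation
#'
#' Litters are the full-sib groups of the last generation.  Cages are
#' filled to `cage_size` with at most `max_littermates` animals of the
#' same litter per cage (the housing rule of the emulated design).
#' Batch, farm-diet-regime group and weaning-weight class are assigned
#' uniformly at random with the configured level counts.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cage_size animals per cage.
#' @param max_littermates littermates allowed per cage (default 2).
#' @param factor_levels named vector with `group`, `batch`, `weight`
#'   level counts (defaults 6, 5, 2).
#' @param seed optional integer seed.
#' @return metadata data.frame (`animal`, `litter`, `cage`, `batch`,
#'   `group`, `weight_class`) for the final-generation animals.
#' @export
assign_litters_cages <- function(ped, cage_size = 4, max_littermates = 2,
                                 factor_levels = c(group = 6, batch = 5,
                                                   weight = 2),
                                 seed = NULL) {
  gen <- attr(ped, "generation")
  if (is.null(gen)) stop("pedigree lacks generation attribute")
  idx <- which(gen == max(gen))
  if (!length(idx)) stop("no final-generation animals")
  with_seed(seed, {
    animals <- ped$animal[idx]
    litter <- paste0("L_", ped$sire[idx], "_", ped$dam[idx])
    ord <- sample(length(animals))
    animals <- animals[ord]; litter <- litter[ord]
    cage <- character(length(animals))
    occupants <- integer(0)           # per-cage occupancy
    litter_in_cage <- list()          # per-cage table of litter counts
    for (k in seq_along(animals)) {
      placed <- FALSE
      for (cg in seq_along(occupants)) {
        if (occupants[cg] >= cage_size) next
        cnt <- litter_in_cage[[cg]][litter[k]]
        if (!is.na(cnt) && cnt >= max_littermates) next
        occupants[cg] <- occupants[cg] + 1L
        tab <- litter_in_cage[[cg]]
        tab[litter[k]] <- if (is.na(cnt)) 1L else cnt + 1L
        litter_in_cage[[cg]] <- tab
        cage[k] <- sprintf("C%03d", cg)
        placed <- TRUE
        break
      }
      if (!placed) {
        occupants <- c(occupants, 1L)
        tab <- integer(0); tab[litter[k]] <- 1L
        litter_in_cage[[length(occupants)]] <- tab
        cage[k] <- sprintf("C%03d", length(occupants))
      }
    }
    data.frame(
      animal = animals, litter = litter, cage = cage,
      batch = paste0("B", sample.int(factor_levels[["batch"]],
                                     length(animals), replace = TRUE)),
      group = paste0("G", sample.int(factor_levels[["group"]],
                                     length(animals), replace = TRUE)),
      weight_class = paste0("W", sample.int(factor_levels[["weight"]],
                                            length(animals), replace = TRUE)),
      stringsAsFactors = FALSE)
  })
}

# Draw the latent linear predictor X beta + u + litter + cage + residual
# with component variances sigma2_P * (h2, l2, c2, 1 - sum).
simulate_linear_predictor <- function(X, Z_L, Z_C, u_obs, true_ratios,
                                      sigma2_P, beta_true) {
  r <- check_simplex(true_ratios)
  n <- nrow(X)
  lit <- rnorm(ncol(Z_L), 0, sqrt(sigma2_P * r[2]))
  cg <- rnorm(ncol(Z_C), 0, sqrt(sigma2_P * r[3]))
  e <- rnorm(n, 0, sqrt(sigma2_P * (1 - sum(r))))
  xb <- if (length(beta_true)) drop(X %*% beta_true) else rep(0, n)
  list(eta = xb + u_obs + drop(Z_L %*% lit) + drop(Z_C %*% cg) + e,
       litter_effects = lit, cage_effects = cg)
}

#' Simulate a trait under the linear mixed model
#'
#' `y_raw = X beta + u + litter + cage + residual` with component
#' variances `sigma2_P * (h2, l2, c2, 1 - h2 - l2 - c2)`, then the
#' integer transformation of [transform_trait()] for the requested trait
#' kind.  For `kind = "otu"` the raw scale must be non-negative; rare
#' negative excursions are clipped to zero with a warning.
#'
#' @param X,Z_L,Z_C design matrices (see [build_design()]).
#' @param u_obs breeding values of the observed animals.
#' @param true_ratios generating `(h2, l2, c2)`.
#' @param sigma2_P generating phenotypic variance.
#' @param beta_true systematic effects (length `ncol(X)`, or empty).
#' @param kind trait kind passed to [transform_trait()].
#' @param seed optional integer seed.
#' @return integer trait vector.
#' @export
simulate_lmm_trait <- function(X, Z_L, Z_C, u_obs, true_ratios, sigma2_P,
                               beta_true = numeric(0), kind = "genus",
                               seed = NULL) {
  with_seed(seed, {
    y <- simulate_linear_predictor(X, Z_L, Z_C, u_obs, true_ratios,
                                   sigma2_P, beta_true)$eta
    if (kind == "otu" && any(y < 0)) {
      warning(sum(y < 0), " negative raw value(s) clipped to 0 for an OTU-kind trait")
      y <- pmax(y, 0)
    }
    transform_trait(y, kind)
  })
}

#' Simulate a trait under the zero-inflated Poisson process
#'
#' The latent log means follow the same linear predictor as the linear
#' model (`lambda* = X beta + u + litter + cage + residual`); each
#' observation is a structural zero with probability `p_structural`, and
#' otherwise Poisson with mean `exp(lambda*)` (clipped at `exp(19)` to
#' keep counts representable, with a warning).
#'
#' @inheritParams simulate_lmm_trait
#' @param p_structural structural-zero probability in \[0, 1).
#' @return non-negative integer count vector.
#' @export
simulate_zip_trait <- function(X, Z_L, Z_C, u_obs, true_ratios, sigma2_P,
                               beta_true = numeric(0), p_structural = 0,
                               seed = NULL) {
  if (p_structural < 0 || p_structural >= 1)
    stop("p_structural must be in [0, 1)")
  with_seed(seed, {
    ls <- simulate_linear_predictor(X, Z_L, Z_C, u_obs, true_ratios,
                                    sigma2_P, beta_true)$eta
    if (any(ls > 19)) {
      warning(sum(ls > 19), " latent log-mean(s) clipped at 19")
      ls <- pmin(ls, 19)
    }
    y <- rpois(length(ls), exp(ls))
    y[runif(length(ls)) < p_structural] <- 0L
    as.integer(y)
  })
}

#' Simulate a complete study
#'
#' Pedigree, litters, cages, systematic factors and one or more traits
#' generated under the linear or zero-inflated Poisson process with known
#' truth, in exactly the shapes the fitting functions accept.
#'
#' @param n_founders,n_generations,litter_size pedigree configuration.
#' @param cage_size,max_littermates housing configuration.
#' @param true_ratios generating `(h2, l2, c2)`.
#' @param sigma2_P generating phenotypic variance (trait-scale for the
#'   linear model, log-scale for ZIP).
#' @param p_structural structural-zero probability (ZIP only).
#' @param model `"lmm"` or `"zip"`.
#' @param trait_kind trait kind for the linear model transformation.
#' @param trait_mean baseline mean of the linear predictor (raw trait
#'   scale for the linear model; log scale for ZIP, where 3 gives
#'   exp-scale means around 20).
#' @param beta_scale systematic effects are drawn uniformly within
#'   `beta_scale` standard deviations around the baseline (default 0.5).
#' @param n_traits number of independent traits to generate.
#' @param factor_levels level counts for group/batch/weight.
#' @param seed optional integer seed; the whole study is reproducible.
#' @return a `vr_study_sim` list: `pedigree`, `metadata`, `traits`
#'   (data.frame, first column `animal`), `design`, `kernels`, `truth`.
#' @export
simulate_study <- function(n_founders = 40, n_generations = 3,
                           litter_size = 4, cage_size = 4,
                           max_littermates = 2,
                           true_ratios = c(h2 = 0.25, l2 = 0.15, c2 = 0.15),
                           sigma2_P = 1, p_structural = 0,
                           model = c("lmm", "zip"), trait_kind = "genus",
                           trait_mean = NULL,
                           beta_scale = 0.5, n_traits = 1,
                           factor_levels = c(group = 6, batch = 5, weight = 2),
                           seed = NULL) {
  model <- match.arg(model)
  trait_mean <- trait_mean %||% if (model == "zip") 3 else 0
  with_seed(seed, {
    ped <- simulate_pedigree(n_founders, n_generations, litter_size)
    metadata <- assign_litters_cages(ped, cage_size, max_littermates,
                                     factor_levels)
    for (v in c("litter", "cage", "batch", "group", "weight_class"))
      metadata[[v]] <- factor(metadata[[v]])
    design <- build_design(metadata)
    sped <- sort_pedigree(ped)
    A <- relationship_matrix(sped)
    kernels <- make_kernels(A, design)
    u_all <- simulate_breeding_values(sped, sigma2_P * true_ratios[[1]])
    u_obs <- u_all[design$animal_ids]
    sdP <- sqrt(sigma2_P)
    p <- ncol(design$X)
    beta_true <- trait_mean +
      runif(p, -beta_scale * sdP, beta_scale * sdP)
    # treatment-coded blocks are contrasts around the group baseline
    beta_true[-seq_len(nlevels(metadata$group))] <-
      runif(p - nlevels(metadata$group), -beta_scale * sdP, beta_scale * sdP)
    traits <- data.frame(animal = design$animal_ids,
                         stringsAsFactors = FALSE)
    for (k in seq_len(n_traits)) {
      traits[[paste0("trait", k)]] <- if (model == "lmm")
        simulate_lmm_trait(design$X, design$Z_L, design$Z_C, u_obs,
                           true_ratios, sigma2_P, beta_true, trait_kind)
      else
        simulate_zip_trait(design$X, design$Z_L, design$Z_C, u_obs,
                           true_ratios, sigma2_P, beta_true, p_structural)
    }
    structure(list(
      pedigree = sped, metadata = metadata, traits = traits,
      design = design, kernels = kernels,
      truth = list(true_ratios = check_simplex(true_ratios),
                   sigma2_P = sigma2_P, p_structural = p_structural,
                   beta_true = beta_true, u = u_obs, model = model,
                   trait_kind = trait_kind)),
      class = "vr_study_sim")
  })
}

#' Write a simulated study to delimited files
#'
#' Emits `pedigree.csv`, `metadata.csv`, `traits.csv` (the dialects the
#' readers accept) and `truth.json`.
#'
#' @param sim a `vr_study_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- as.data.frame(sim$pedigree)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  paths <- file.path(dir, c("pedigree.csv", "metadata.csv", "traits.csv",
                            "truth.json"))
  write.table(ped, paths[1], sep = ",", row.names = FALSE, quote = FALSE)
  write.table(sim$metadata, paths[2], sep = ",", row.names = FALSE,
              quote = FALSE)
  write.table(sim$traits, paths[3], sep = ",", row.names = FALSE,
              quote = FALSE)
  truth <- sim$truth
  truth$u <- unname(truth$u)
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
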
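#' Read the per-animal metadata table
#'
#' Delimited text with named columns `animal`, `litter`, `cage`, `batch`,
#' `group`, `weight_class`.  `group` is the combination of breeding farm,
#' diet and feeding regime.
#'
#' @param path delimited text file (comma or tab autodetected).
#' @return data.frame with character id column and factor columns.
#' @export
read_metadata <- function(path) {
  df <- read_delim_auto(path, required = c("animal", "litter", "cage",
                                           "batch", "group", "weight_class"))
  df$animal <- as.character(df$animal)
  for (v in c("litter", "cage", "batch", "group", "weight_class"))
    df[[v]] <- factor(df[[v]])
  validate_metadata(df)
  df
}

validate_metadata <- function(metadata) {
  req <- c("animal", "litter", "cage", "batch", "group", "weight_class")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(metadata) == 0L) stop("empty metadata")
  for (v in req) {
    bad <- is.na(metadata[[v]]) | as.character(metadata[[v]]) == ""
    if (any(bad))
      stop("animal(s) with missing ", v, ": ",
           paste(head(metadata$animal[bad], 5L), collapse = ", "))
  }
  invisible(metadata)
}

#' Read a trait table
#'
#' Delimited text, animals in rows, traits in columns, first column the
#' animal id.
#'
#' @param path delimited text file.
#' @return data.frame whose first column is `animal` (character), the rest
#'   numeric trait columns.
#' @export
read_traits <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1] <- "animal"
  df$animal <- as.character(df$animal)
  for (j in seq_along(df)[-1]) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Build design matrices for the systematic, litter and cage effects
#'
#' The systematic-effects matrix `X` uses full dummy coding for the
#' farm-diet-regime combination (`group`) and treatment (drop-first)
#' coding for `batch` and `weight_class`, which avoids a redundant global
#' intercept while keeping `X` full rank; at the study's level counts
#' (6, 5, 2) this gives 6 + 4 + 1 = 11 columns.  `Z_L` and `Z_C` are 0/1
#' incidence matrices to litter and cage (one 1 per row).
#'
#' @param metadata data.frame as validated by [read_metadata()].
#' @return a `vr_design` list with elements `X`, `Z_L`, `Z_C`,
#'   `animal_ids`.
#' @export
build_design <- function(metadata) {
  validate_metadata(metadata)
  md <- metadata
  for (v in c("litter", "cage", "batch", "group", "weight_class"))
    md[[v]] <- factor(md[[v]])

  blocks <- list()
  g <- md$group
  if (nlevels(g) >= 2L) {
    blocks$group <- onehot(g, prefix = "group")
  } else {
    warning("factor 'group' has a single level; collapsing to an intercept column")
    blocks$group <- matrix(1, nrow(md), 1, dimnames = list(NULL, "group"))
  }
  for (v in c("batch", "weight_class")) {
    f <- md[[v]]
    if (nlevels(f) >= 2L) {
      blocks[[v]] <- onehot(f, prefix = v)[, -1, drop = FALSE]
    } else {
      warning("factor '", v, "' has a single level; dropping its block")
    }
  }
  X <- do.call(cbind, blocks)
  if (qr(X)$rank < ncol(X))
    stop("systematic-effects design is rank deficient (confounded factors)")
  Z_L <- onehot(md$litter, prefix = "litter")
  Z_C <- onehot(md$cage, prefix = "cage")
  structure(list(X = X, Z_L = Z_L, Z_C = Z_C,
                 animal_ids = md$animal),
            class = "vr_design")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 0/1 incidence matrix of a factor (robust to single-level factors)
onehot <- function(f, prefix = "") {
  f <- factor(f)
  m <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, paste0(prefix, levels(f))))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Integer transformation of a microbial trait
#'
#' Normalized OTU counts are multiplied by 100 and rounded to the nearest
#' integer; genus relative abundances and alpha-diversity indices are
#' first standardized (mean 0, sample sd 1), then multiplied by 100 and
#' rounded.  Rounding is half-away-from-zero.
#'
#' @param values numeric vector.
#' @param kind one of `"otu"`, `"genus"`, `"diversity"`.
#' @return integer vector.
#' @export
transform_trait <- function(values, kind = c("otu", "genus", "diversity")) {
  kind <- match.arg(kind)
  if (!length(values)) stop("empty trait vector")
  if (kind == "otu") {
    if (any(values < 0)) stop("OTU trait values must be non-negative")
    return(as.integer(round_half_away(values * 100)))
  }
  s <- sd(values)
  if (!is.finite(s) || s <= 0)
    stop("cannot standardize a constant trait (zero standard deviation)")
  as.integer(round_half_away((values - mean(values)) / s * 100))
}

#' Frequency of a trait across animals and its frequency class
#'
#' Returns the percentage of animals with a nonzero value and the
#' frequency class used to categorize OTU: `[5,10]`, `(10,25]`, `(25,50]`,
#' `(50,75]`, `(75,100]` (percent).  Traits present in fewer than 5% of
#' the animals are flagged as excluded.
#'
#' @param values integer vector (one value per animal).
#' @return list with `frequency` (percent nonzero), `class` (character)
#'   and `excluded` (logical).
#' @export
trait_frequency_class <- function(values) {
  if (!length(values)) stop("empty trait vector")
  f <- 100 * mean(values != 0)
  if (f < 5) {
    cls <- "<5"
    excluded <- TRUE
  } else {
    excluded <- FALSE
    cls <- if (f <= 10) "[5,10]"
      else if (f <= 25) "(10,25]"
      else if (f <= 50) "(25,50]"
      else if (f <= 75) "(50,75]"
      else "(75,100]"
  }
  list(frequency = f, class = cls, excluded = excluded)
}
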
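#' Read and validate a three-column pedigree
#'
#' Reads a pedigree table with columns animal, sire, dam (comma- or
#' tab-delimited, header optional) and validates it: no duplicate animals,
#' no animal that is its own parent, no cycles in the parent graph.
#' Animals with both parents unknown are founders.
#'
#' @param source path to a delimited text file, or a data.frame with three
#'   columns (animal, sire, dam).
#' @param unknown token coding an unknown parent (default `"0"`); `NA` is
#'   always accepted as unknown too.
#' @param missing_parent what to do when a parent id never appears as an
#'   animal: `"founder"` (default) silently-but-audibly promotes it to a
#'   founder record with a warning; `"error"` fails.
#' @return a `pedigree` object: a data.frame with character columns
#'   `animal`, `sire`, `dam` (unknown parents are `NA`).
#' @export
read_pedigree <- function(source, unknown = "0",
                          missing_parent = c("founder", "error")) {
  missing_parent <- match.arg(missing_parent)
  if (is.character(source) && length(source) == 1L) {
    df <- read_delim_auto(source)
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 3L)
    stop("pedigree must have three columns: animal, sire, dam")
  df <- df[, 1:3]
  names(df) <- c("animal", "sire", "dam")
  for (j in 1:3) df[[j]] <- trimws(as.character(df[[j]]))
  df$sire[df$sire %in% unknown | df$sire == ""] <- NA_character_
  df$dam[df$dam %in% unknown | df$dam == ""] <- NA_character_

  if (anyNA(df$animal) || any(df$animal == ""))
    stop("missing animal identifier in pedigree")
  dup <- df$animal[duplicated(df$animal)]
  if (length(dup))
    stop("duplicate animal id(s) in pedigree: ", paste(unique(dup), collapse = ", "))
  own <- df$animal == df$sire | df$animal == df$dam
  own[is.na(own)] <- FALSE
  if (any(own))
    stop("animal equal to its own parent: ", paste(df$animal[own], collapse = ", "))

  parents <- unique(c(df$sire, df$dam))
  parents <- parents[!is.na(parents)]
  orphan <- setdiff(parents, df$animal)
  if (length(orphan)) {
    if (missing_parent == "error")
      stop("parent id(s) never defined as animals: ", paste(orphan, collapse = ", "))
    warning("promoting ", length(orphan),
            " referenced-but-undefined parent id(s) to founders: ",
            paste(head(orphan, 5L), collapse = ", "),
            if (length(orphan) > 5L) ", ..." else "")
    df <- rbind(data.frame(animal = orphan, sire = NA_character_,
                           dam = NA_character_, stringsAsFactors = FALSE), df)
  }
  ped <- structure(df, class = c("pedigree", "data.frame"), row.names = seq_len(nrow(df)))
  # cycle check: sorting fails on a cycle
  invisible(sort_pedigree(ped))
  ped
}

#' Topologically sort a pedigree
#'
#' Reorders records so that every parent precedes all of its offspring
#' (a precondition of the tabular relationship-matrix recursion).  The
#' order is stable: among animals available at the same step, original
#' order is preserved.
#'
#' @param ped a `pedigree` object (or data.frame with animal/sire/dam).
#' @return the reordered `pedigree`.
#' @export
sort_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  # parent indices; tokens that resolve to no animal count as unknown
  si <- unname(pos[as.character(ped$sire)])
  di <- unname(pos[as.character(ped$dam)])
  placed <- logical(n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining)) {
    sire_ok <- ifelse(is.na(si[remaining]), TRUE, placed[si[remaining]])
    dam_ok <- ifelse(is.na(di[remaining]), TRUE, placed[di[remaining]])
    ready <- remaining[sire_ok & dam_ok]
    if (!length(ready))
      stop("cycle detected in pedigree involving: ",
           paste(head(ped$animal[remaining], 5L), collapse = ", "))
    order_out <- c(order_out, ready)
    placed[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  structure(ped[order_out, , drop = FALSE],
            class = c("pedigree", "data.frame"),
            row.names = seq_len(n))
}

is_sorted_pedigree <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  si <- pos[ped$sire]
  di <- pos[ped$dam]
  all(is.na(si) | si < pos) && all(is.na(di) | di < pos)
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A from a sorted
#' pedigree by the tabular recursion: for j < i,
#' `a(i,j) = 0.5 (a(j, sire_i) + a(j, dam_i))` and
#' `a(i,i) = 1 + 0.5 a(sire_i, dam_i)`, an unknown parent contributing 0.
#' Founders are assumed non-inbred.
#'
#' @param ped a sorted `pedigree` (see [sort_pedigree()]).
#' @return a symmetric matrix with dimnames equal to the animal ids, in
#'   pedigree order.
#' @export
relationship_matrix <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  if (!is_sorted_pedigree(ped))
    stop("pedigree is not sorted; call sort_pedigree() first")
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  si <- unname(pos[ped$sire])
  di <- unname(pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (!is.na(s)) A[s, j] else 0
      row_d <- if (!is.na(d)) A[d, j] else 0
      aij <- 0.5 * (row_s + row_d)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
  }
  A
}

#' Observation-level additive kernel
#'
#' Extracts the kernel `Z_A A Z_A'` for a set of observed animals (one
#' record per animal), i.e. the submatrix of A in observation order.
#'
#' @param A relationship matrix from [relationship_matrix()].
#' @param observed character vector of observed animal ids.
#' @return symmetric matrix of dimension `length(observed)`.
#' @export
observation_kernel <- function(A, observed) {
  observed <- as.character(observed)
  missing <- setdiff(observed, rownames(A))
  if (length(missing))
    stop("observed animal(s) absent from pedigree: ",
         paste(head(missing, 5L), collapse = ", "))
  A[observed, observed, drop = FALSE]
}

# comma/tab autodetected delimited reader with header sniffing
read_delim_auto <- function(path, required = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- any(tolower(trimws(fields)) %in%
                c("animal", "sire", "dam", "litter", "cage", "id", "trait"))
  df <- read.table(path, sep = sep, header = header,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop("missing required column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  df
}
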
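#' Pedigree tables
#'
#' A pedigree is a tibble with character columns `animal`, `sire`, `dam`
#' (unknown parents coded `NA`), ordered so that parents precede their
#' offspring. All relationship-matrix code in this package requires that
#' ordering and verifies it on entry.
#'
#' @param animal,sire,dam character vectors of ids; unknown parents as `NA`
#'   or `"0"` (converted to `NA`).
#' @param validate check ordering and acyclicity (default `TRUE`).
#' @return A tibble of class `ped_tbl` with columns `animal`, `sire`, `dam`.
#' @examples
#' pedigree(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"))
#' @export
pedigree <- function(animal, sire, dam, validate = TRUE) {
  ped <- tibble::tibble(
    animal = as.character(animal),
    sire   = dplyr::na_if(as.character(sire), "0"),
    dam    = dplyr::na_if(as.character(dam), "0")
  )
  ped <- tibble::new_tibble(ped, class = "ped_tbl")
  if (validate) validate_pedigree(ped)
  ped
}

#' Validate a pedigree table
#'
#' Checks id uniqueness, that every known parent appears as an animal in an
#' earlier row, and that no animal is its own ancestor.
#'
#' @param ped a pedigree tibble (see [pedigree()]).
#' @return `ped`, invisibly.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  if (anyNA(ped$animal)) stop_wssgwas("pedigree has missing animal ids", "ped_invalid")
  if (anyDuplicated(ped$animal)) {
    dup <- ped$animal[duplicated(ped$animal)][1]
    stop_wssgwas(paste0("duplicated animal id: ", dup), "ped_invalid")
  }
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- !is.na(par)
    missing_par <- known & is.na(idx[par])
    if (any(missing_par)) {
      row <- which(missing_par)[1]
      stop_wssgwas(
        paste0("row ", row, " (animal ", ped$animal[row], "): ", col, " ",
               par[row], " does not appear as an animal"),
        "ped_unordered"
      )
    }
    late <- known & idx[par] >= seq_len(nrow(ped))
    if (any(late)) {
      row <- which(late)[1]
      stop_wssgwas(
        paste0("pedigree not parent-first ordered: row ", row, " (animal ",
               ped$animal[row], ") has ", col, " ", par[row],
               " in a later or same row"),
        "ped_unordered"
      )
    }
  }
  invisible(ped)
}

#' Topologically sort an unordered pedigree
#'
#' Reorders rows so every parent precedes its offspring (Kahn's algorithm)
#' and reports the permutation applied. Cycles (an animal its own ancestor)
#' are an error.
#'
#' @param ped a pedigree tibble in any row order.
#' @return The reordered pedigree with an attribute `"permutation"` giving
#'   the original row index of each output row.
#' @export
order_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  parents <- cbind(idx[ped$sire], idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- ped$animal[setdiff(seq_len(n), out)]
    stop_wssgwas(
      paste0("pedigree contains a cycle involving: ",
             paste(head(bad, 5), collapse = ", ")),
      "ped_cycle"
    )
  }
  res <- pedigree(ped$animal[out], ped$sire[out], ped$dam[out])
  for (extra in setdiff(names(ped), c("animal", "sire", "dam"))) {
    res[[extra]] <- ped[[extra]][out]
  }
  attr(res, "permutation") <- out
  res
}

#' Prune a pedigree to informative animals
#'
#' Retains the given animals (typically those with a phenotype or genotype)
#' plus all of their ancestors, preserving row order. Pruning is idempotent.
#'
#' @param ped an ordered pedigree tibble.
#' @param keep_ids character vector of animal ids to anchor the pruning;
#'   ids not present in the pedigree are ignored. An empty set yields an
#'   empty pedigree.
#' @return The pruned pedigree tibble.
#' @export
prune_pedigree <- function(ped, keep_ids) {
  validate_pedigree(ped)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  keep <- logical(nrow(ped))
  keep[idx[intersect(unique(as.character(keep_ids)), ped$animal)]] <- TRUE
  # parents precede offspring, so one reverse sweep closes over ancestors
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      for (p in c(ped$sire[i], ped$dam[i])) {
        if (!is.na(p)) keep[idx[p]] <- TRUE
      }
    }
  }
  ped[keep, , drop = FALSE]
}

#' Read / write pedigree CSV
#'
#' Plain CSV with columns `animal,sire,dam`; `0` or empty denotes an unknown
#' parent. Input in arbitrary row order is topologically sorted on read.
#'
#' @param path file path.
#' @return `read_pedigree_csv()`: an ordered pedigree tibble.
#' @export
read_pedigree_csv <- function(path) {
  if (!file.exists(path)) {
    stop_wssgwas(paste0("pedigree file not found: ", path), "io_missing_file")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  ped <- pedigree(raw$animal, raw$sire, raw$dam, validate = FALSE)
  order_pedigree(ped)
}

#' @rdname read_pedigree_csv
#' @param ped a pedigree tibble.
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- tibble::tibble(
    animal = ped$animal,
    sire = tidyr::replace_na(ped$sire, "0"),
    dam  = tidyr::replace_na(ped$dam, "0")
  )
  readr::write_csv(out, path)
  invisible(path)
}
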
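#' Pedigree objects
#'
#' A pedigree is a data frame with character columns `animal`, `sire` and
#' `dam` ("0" codes an unknown parent), stored in topological order so that
#' every parent precedes its offspring. Extra columns (e.g. `generation`,
#' `sex`, `cg` from the simulator) are carried along.
#'
#' @param df data frame with at least columns `animal`, `sire`, `dam`.
#' @return A data frame of class `pedigree`, topologically sorted.
#' @export
as_pedigree <- function(df) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  df$animal <- as.character(df$animal)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  df$sire[is.na(df$sire) | df$sire == ""] <- "0"
  df$dam[is.na(df$dam) | df$dam == ""] <- "0"
  if (anyDuplicated(df$animal))
    stop("duplicate animal id(s): ",
         paste(unique(df$animal[duplicated(df$animal)]), collapse = ", "))
  if (any(df$animal == "0")) stop("'0' is reserved for unknown parents")
  ord <- ped_toposort(df$animal, df$sire, df$dam)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

# Kahn's algorithm; parents not listed as animals are treated as unknown
# founder contributions (kept as-is in sire/dam but not ordered).
ped_toposort <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- idx[sire]  # NA when parent unknown or unlisted
  di <- idx[dam]
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- animal[setdiff(seq_len(n), out)]
    stop("pedigree cycle involving: ", paste(bad, collapse = ", "))
  }
  out
}

#' Read a pedigree CSV
#'
#' Expects columns `animal,sire,dam`; unknown parents coded `0` or empty.
#' Animals are returned in topological order; cycles and duplicated ids are
#' rejected.
#'
#' @param path path to a CSV file.
#' @return A [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  as_pedigree(df)
}

#' Write a pedigree CSV
#'
#' @param ped a `pedigree` object.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# integer parent indices (0 = unknown) against the pedigree's own order
ped_parent_index <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  s <- idx[ped$sire]; d <- idx[ped$dam]
  s[is.na(s)] <- 0L; d[is.na(d)] <- 0L
  list(sire = unname(s), dam = unname(d))
}
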
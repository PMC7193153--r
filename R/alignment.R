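#' Amino-acid alignment container
#'
#' A light S3 container over equal-length amino-acid strings: the 20 standard
#' residues plus gap \code{'-'} and unknown \code{'X'}. An optional reference
#' sequence name and inclusive reference-coordinate window (e.g. 31..311 in
#' bovine-RH1 numbering) travel with the alignment and drive site selection in
#' the likelihood and reconstruction code.
#'
#' @param names Unique sequence identifiers.
#' @param seqs Character vector of equal-length sequences.
#' @param reference_name Optional name of the numbering reference sequence.
#' @param site_window Optional inclusive reference-position interval,
#'   length-2 integer vector.
#' @return An \code{aa_alignment} object.
#' @export
aa_alignment <- function(names, seqs, reference_name = NULL, site_window = NULL) {
  names <- as.character(names)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(names) != length(seqs)) stop("names and seqs differ in length")
  if (anyDuplicated(names)) {
    stop("duplicate sequence names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  nc <- nchar(seqs)
  if (length(unique(nc)) > 1L) {
    off <- names[nc != nc[1L]][1L]
    stop("ragged alignment: sequence '", off, "' has length ",
         nc[names == off][1L], ", expected ", nc[1L])
  }
  if (!is.null(site_window)) {
    site_window <- as.integer(site_window)
    stopifnot(length(site_window) == 2L, site_window[1L] <= site_window[2L])
  }
  structure(list(names = names, seqs = seqs,
                 reference_name = reference_name, site_window = site_window),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", length(x$names), "sequences x",
      nchar(x$seqs[1L]), "columns\n")
  if (!is.null(x$reference_name)) {
    cat("reference:", x$reference_name,
        if (!is.null(x$site_window))
          paste0("(window ", x$site_window[1L], "..", x$site_window[2L], ")"),
        "\n")
  }
  invisible(x)
}

#' Number of alignment columns
#' @param aln An \code{aa_alignment}.
#' @return Integer column count.
#' @export
n_columns <- function(aln) nchar(aln$seqs[1L])

# alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$names
  m
}

#' Read / write FASTA alignments
#'
#' Thin wrappers over \pkg{Biostrings} that normalize to the package's
#' conventions: letters uppercased, \code{'.'} gaps rewritten as \code{'-'},
#' duplicate names and ragged rows rejected. \code{read_fasta(write_fasta(x))}
#' is the identity.
#'
#' @param path File path.
#' @param reference_name,site_window Passed to \code{\link{aa_alignment}}.
#' @return \code{read_fasta}: an \code{aa_alignment}.
#' @export
read_fasta <- function(path, reference_name = NULL, site_window = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  aa_alignment(names(ss), as.character(ss),
               reference_name = reference_name, site_window = site_window)
}

#' @rdname read_fasta
#' @param aln An \code{aa_alignment}.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$names
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Map alignment columns to reference-sequence numbering
#'
#' Gives every alignment column the 1-based ungapped position of the named
#' reference sequence (the vision-science convention numbers opsin sites by
#' bovine RH1). Columns where the reference carries a gap are unnumbered
#' (\code{NA}). When \code{window} (or the alignment's own \code{site_window})
#' is set, the returned map is restricted to columns whose reference position
#' falls inside the inclusive window.
#'
#' @param aln An \code{aa_alignment} containing the reference.
#' @param reference_name Reference sequence identifier; defaults to the
#'   alignment's own \code{reference_name}.
#' @param window Optional inclusive position interval overriding
#'   \code{aln$site_window}.
#' @return A data frame with \code{column} (alignment column index) and
#'   \code{position} (reference position); unnumbered columns are dropped when
#'   a window is in force, otherwise reported with \code{position = NA}.
#' @export
map_reference_numbering <- function(aln, reference_name = aln$reference_name,
                                    window = aln$site_window) {
  if (is.null(reference_name)) stop("no reference sequence name given")
  i <- match(reference_name, aln$names)
  if (is.na(i)) stop("reference sequence '", reference_name, "' absent from alignment")
  ref <- strsplit(aln$seqs[i], "")[[1L]]
  is_res <- !(ref %in% c("-"))
  pos <- rep(NA_integer_, length(ref))
  pos[is_res] <- seq_len(sum(is_res))
  map <- data.frame(column = seq_along(ref), position = pos)
  if (!is.null(window)) {
    map <- map[!is.na(map$position) &
               map$position >= window[1L] & map$position <= window[2L], ,
               drop = FALSE]
    if (nrow(map) == 0L) {
      warning("reference window ", window[1L], "..", window[2L],
              " retains no alignment columns")
    }
    rownames(map) <- NULL
  }
  map
}

#' Alignment columns retained for analysis
#'
#' The column indices used by the likelihood, reconstruction and concordance
#' code: all columns when no reference/window is set, else the windowed
#' reference-numbered columns.
#'
#' @param aln An \code{aa_alignment}.
#' @return Integer vector of column indices.
#' @export
retained_columns <- function(aln) {
  if (is.null(aln$reference_name) || is.null(aln$site_window)) {
    return(seq_len(n_columns(aln)))
  }
  map_reference_numbering(aln)$column
}

#' Observed amino-acid frequencies of an alignment
#'
#' Empirical residue frequencies over all (non-gap, non-X) cells, for use as
#' "+F" frequencies in \code{\link{build_rate_matrix}}. A small pseudocount
#' keeps absent residues strictly positive, as a valid stationary distribution
#' requires.
#'
#' @param aln An \code{aa_alignment}.
#' @param pseudocount Added to each residue count (default 0.5).
#' @return Named length-20 probability vector in \code{\link{aa_states}} order.
#' @export
empirical_frequencies <- function(aln, pseudocount = 0.5) {
  m <- unlist(strsplit(aln$seqs, ""), use.names = FALSE)
  counts <- table(factor(m, levels = aa_states()))
  f <- as.numeric(counts) + pseudocount
  f <- f / sum(f)
  names(f) <- aa_states()
  f
}
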
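#' Define an insertion strategy
#'
#' An insertion strategy is a recipe for placing a foreign epitope into a
#' backbone protein: where the insert goes, how many backbone residues
#' are deleted at that point, and which linkers flank the insert.
#' Coordinates are 0-based; insertion occurs before `position`, and
#' `n_deleted` residues are removed forward from `position`.
#'
#' @param id Short label, e.g. `"A"`.
#' @param position 0-based insertion index into the backbone.
#' @param n_deleted Number of backbone residues deleted at `position`.
#' @param linker_before,linker_after Residue strings (possibly empty).
#' @return Object of class `insertion_strategy` (a list).
#' @export
insertion_strategy <- function(id, position, n_deleted = 0L,
                               linker_before = "", linker_after = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            position >= 0L, n_deleted >= 0L)
  check_canonical(linker_before, paste0("linker_before of strategy ", id),
                  allow_empty = TRUE)
  check_canonical(linker_after, paste0("linker_after of strategy ", id),
                  allow_empty = TRUE)
  structure(list(id = id, position = as.integer(position),
                 n_deleted = as.integer(n_deleted),
                 linker_before = linker_before, linker_after = linker_after),
            class = "insertion_strategy")
}

check_canonical <- function(seq, what, allow_empty = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    if (allow_empty) return(invisible(TRUE))
    stop(what, ": empty sequence")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% aa_residues()))
  if (length(bad) > 0L) {
    stop(what, ": non-canonical residue '", chars[bad[1L]],
         "' at position ", bad[1L])
  }
  invisible(TRUE)
}

#' Build a chimeric sequence from backbone, insert, and strategy
#'
#' @param backbone,insert Canonical residue strings.
#' @param strategy An [insertion_strategy()].
#' @return The chimeric residue string
#'   `backbone[0:pos] + linker_before + insert + linker_after +
#'   backbone[pos+n_deleted:]` (0-based half-open slices).
#' @export
apply_insertion_strategy <- function(backbone, insert, strategy) {
  stopifnot(inherits(strategy, "insertion_strategy"))
  check_canonical(backbone, "backbone")
  check_canonical(insert, "insert")
  n <- nchar(backbone)
  pos <- strategy$position
  del <- strategy$n_deleted
  if (pos > n || pos + del > n) {
    stop("strategy '", strategy$id, "': position ", pos, " + ", del,
         " deletions exceeds backbone length ", n)
  }
  paste0(substr(backbone, 1L, pos),
         strategy$linker_before, insert, strategy$linker_after,
         substr(backbone, pos + del + 1L, n))
}

#' Build the full insert x strategy construct grid
#'
#' Every combination of insert peptide and insertion strategy yields one
#' chimeric construct, so `length(inserts) * length(strategies)`
#' constructs in total with deterministic ids `"<insert>_<strategy>"`.
#'
#' @param backbone Canonical residue string.
#' @param inserts Named character vector (names are insert ids) or list.
#' @param strategies List of [insertion_strategy()] objects.
#' @return `data.frame` with columns id, insert_id, strategy_id, sequence.
#' @export
build_construct_grid <- function(backbone, inserts, strategies) {
  inserts <- unlist(inserts)
  if (length(inserts) == 0L || length(strategies) == 0L) {
    return(data.frame(id = character(0L), insert_id = character(0L),
                      strategy_id = character(0L), sequence = character(0L),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(inserts)) || any(!nzchar(names(inserts)))) {
    stop("inserts must be named by insert id")
  }
  if (anyDuplicated(names(inserts))) {
    stop("duplicate insert id(s): ",
         paste(unique(names(inserts)[duplicated(names(inserts))]),
               collapse = ", "))
  }
  sids <- vapply(strategies, function(s) s$id, character(1L))
  if (anyDuplicated(sids)) stop("duplicate strategy id(s)")
  rows <- vector("list", length(inserts) * length(strategies))
  r <- 0L
  for (st in strategies) {
    for (i in seq_along(inserts)) {
      r <- r + 1L
      rows[[r]] <- data.frame(
        id = paste0(names(inserts)[i], "_", st$id),
        insert_id = names(inserts)[i],
        strategy_id = st$id,
        sequence = apply_insertion_strategy(backbone, inserts[[i]], st),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$insert_id, out$strategy_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Whole-sequence hydrophobicity feature
#'
#' The feature of a sequence under a scale is the plain sum of the
#' scale's value over every residue — composition-only, not
#' length-normalized, so residue order never matters.
#'
#' @param sequence Canonical residue string.
#' @param s An `aa_scale`.
#' @return A single real feature value.
#' @export
compute_feature <- function(sequence, s) {
  stopifnot(inherits(s, "aa_scale"))
  check_canonical(sequence, "sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(as.numeric(s)[match(chars, aa_residues())])
}

#' Residue-count matrix of a set of sequences
#'
#' Counts each canonical residue per sequence.  Since features are sums,
#' `residue_counts(x) %*% scale` reproduces [compute_feature()] exactly;
#' all heavier routines work from this matrix.
#'
#' @param sequences Character vector of canonical residue strings.
#' @return Integer matrix, `length(sequences)` x 20, columns in
#'   canonical residue order.
#' @export
residue_counts <- function(sequences) {
  res <- aa_residues()
  out <- matrix(0L, nrow = length(sequences), ncol = 20L,
                dimnames = list(names(sequences), res))
  for (i in seq_along(sequences)) {
    check_canonical(sequences[i], paste0("sequence ", i))
    chars <- strsplit(sequences[i], "", fixed = TRUE)[[1L]]
    tab <- tabulate(match(chars, res), nbins = 20L)
    out[i, ] <- tab
  }
  out
}

#' Feature matrix of constructs x scales
#'
#' @param constructs `data.frame` with columns `id` and `sequence`.
#' @param table A `scale_table`.
#' @return Numeric matrix, rows keyed by construct id, columns by scale
#'   name; cell (p, s) is the Eq.-style feature sum of sequence p under
#'   scale s.
#' @export
build_feature_matrix <- function(constructs, table) {
  stopifnot(inherits(table, "scale_table"),
            is.data.frame(constructs), nrow(constructs) > 0L,
            all(c("id", "sequence") %in% names(constructs)))
  seqs <- structure(constructs$sequence, names = constructs$id)
  counts <- tryCatch(residue_counts(seqs), error = function(e) {
    # re-raise with the offending construct id instead of a row index
    m <- regmatches(conditionMessage(e),
                    regexec("^sequence ([0-9]+)", conditionMessage(e)))[[1L]]
    if (length(m) == 2L) {
      stop("construct '", constructs$id[as.integer(m[2L])], "': ",
           sub("^sequence [0-9]+: ", "", conditionMessage(e)), call. = FALSE)
    }
    stop(e)
  })
  fm <- counts %*% table$values
  rownames(fm) <- constructs$id
  fm
}

#' Read sequences from a FASTA file
#'
#' Uses Biostrings when available.  Description lines carry the sequence
#' id (first whitespace-separated token).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    out <- as.character(x)
    names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1L), 1L)
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(seq_along(id), function(i) {
    paste0(lines[!hdr & grp == i], collapse = "")
  }, character(1L))
  structure(toupper(gsub("\\s", "", seqs)), names = id)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(c(paste0(">", names(sequences)[i]), sequences[[i]]), con)
  }
  invisible(path)
}
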
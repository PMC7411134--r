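#' Canonical amino acid alphabet
#'
#' The 20 canonical one-letter residue codes, in the fixed order used for
#' all scale vectors and residue-count matrices in this package.
#'
#' @return Character vector of length 20.
#' @export
aa_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct an amino acid hydrophobicity scale
#'
#' A scale assigns one real hydrophobicity-like value to each of the 20
#' canonical residues.  Whole-sequence features are sums of these values,
#' so a scale is the model's only physicochemical prior.
#'
#' @param name Scale identifier.
#' @param values Named numeric vector with exactly one finite value per
#'   canonical residue (any order; reordered internally).
#' @return An object of class `aa_scale`: named numeric vector of length
#'   20 in canonical residue order, with attribute `name`.
#' @export
aa_scale <- function(name, values) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  res <- aa_residues()
  if (is.null(names(values))) {
    stop("scale values must be named by one-letter residue codes")
  }
  extra <- setdiff(names(values), res)
  if (length(extra) > 0L) {
    stop("non-canonical residue(s) in scale '", name, "': ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(res, names(values))
  if (length(missing) > 0L) {
    stop("scale '", name, "' is missing residue(s): ",
         paste(missing, collapse = ", "))
  }
  v <- as.numeric(values[res])
  if (any(!is.finite(v))) {
    stop("scale '", name, "' contains non-finite values")
  }
  names(v) <- res
  structure(v, name = name, class = "aa_scale")
}

scale_name <- function(s) attr(s, "name")

#' @export
print.aa_scale <- function(x, ...) {
  cat("<aa_scale> ", scale_name(x), "\n", sep = "")
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

#' Construct a table of hydrophobicity scales
#'
#' @param scales List of `aa_scale` objects, or a 20 x k numeric matrix
#'   with residue rownames and scale colnames.
#' @param provenance One of `"literature"`, `"synthesized"`, `"optimized"`.
#' @return Object of class `scale_table`: list with `values` (20 x k
#'   matrix, rows in canonical residue order) and `provenance`.
#' @export
scale_table <- function(scales, provenance = c("literature", "synthesized",
                                               "optimized")) {
  provenance <- match.arg(provenance)
  res <- aa_residues()
  if (is.matrix(scales)) {
    if (is.null(rownames(scales)) || is.null(colnames(scales))) {
      stop("scale matrix needs residue rownames and scale colnames")
    }
    scales <- lapply(colnames(scales), function(nm) {
      aa_scale(nm, scales[, nm])
    })
  }
  stopifnot(length(scales) >= 1L)
  nms <- vapply(scales, scale_name, character(1L))
  if (anyDuplicated(nms)) {
    stop("duplicate scale name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  values <- vapply(scales, as.numeric, numeric(20L))
  dimnames(values) <- list(res, nms)
  structure(list(values = values, provenance = provenance),
            class = "scale_table")
}

#' @export
print.scale_table <- function(x, ...) {
  cat("<scale_table> ", ncol(x$values), " scale(s), provenance: ",
      x$provenance, "\n", sep = "")
  cat(" ", paste(head(colnames(x$values), 8L), collapse = ", "),
      if (ncol(x$values) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

n_scales <- function(t) ncol(t$values)

table_scale <- function(t, name) aa_scale(name, t$values[, name])

#' Read a wide-CSV hydrophobicity scale table
#'
#' Dialect: first column `residue` holds one-letter codes, every further
#' column is one scale; UTF-8, `.` decimal.
#'
#' @param path File path.
#' @param provenance Provenance tag for the resulting table.
#' @return A `scale_table`.
#' @export
load_scale_table <- function(path, provenance = "literature") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("scale table needs a residue column plus >= 1 scale")
  res_col <- as.character(df[[1L]])
  missing <- setdiff(aa_residues(), res_col)
  if (length(missing) > 0L) {
    stop("scale table is missing residue row(s): ",
         paste(missing, collapse = ", "))
  }
  scales <- lapply(names(df)[-1L], function(nm) {
    col <- df[[nm]]
    if (is.character(col)) col <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(col))
    if (length(bad) > 0L) {
      stop("non-numeric value in scale '", nm, "', residue row '",
           res_col[bad[1L]], "'")
    }
    aa_scale(nm, structure(as.numeric(col), names = res_col))
  })
  scale_table(scales, provenance = provenance)
}

#' Write a scale table in the wide-CSV dialect read by [load_scale_table()]
#'
#' @param t A `scale_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scale_table <- function(t, path) {
  stopifnot(inherits(t, "scale_table"))
  df <- data.frame(residue = rownames(t$values), t$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Center a scale and rescale it to unit sample variance
#'
#' Uses the n-1 (sample) variance denominator.  Idempotent.
#'
#' @param s An `aa_scale` (or bare numeric vector of length 20).
#' @return The normalized `aa_scale`.
#' @export
normalize_scale <- function(s) {
  nm <- if (inherits(s, "aa_scale")) scale_name(s) else "scale"
  v <- as.numeric(s)
  stopifnot(length(v) == 20L, all(is.finite(v)))
  sdv <- sd(v)
  if (sdv == 0) stop("degenerate scale '", nm, "': all 20 values equal")
  out <- (v - mean(v)) / sdv
  aa_scale(nm, structure(out, names = aa_residues()))
}

#' Drop reversed duplicates from a scale table
#'
#' A pair of scales with Pearson correlation <= -0.999 (after
#' normalization) is treated as one scale published in two orientations;
#' the later (reversed) member is removed.  The threshold tolerates
#' rounding in published tables.
#'
#' @param t A `scale_table`.
#' @param threshold Correlation at or below which a pair counts as
#'   reversed duplicates.
#' @return The deduplicated `scale_table`; removals are reported via
#'   `message()` and recorded in the `"removed"` attribute.
#' @export
dedupe_reversed <- function(t, threshold = -0.999) {
  stopifnot(inherits(t, "scale_table"))
  k <- n_scales(t)
  norm <- apply(t$values, 2L, function(v) as.numeric(normalize_scale(
    aa_scale("x", structure(v, names = aa_residues())))))
  keep <- rep(TRUE, k)
  removed <- character(0L)
  for (j in seq_len(k)) {
    if (!keep[j]) next
    if (j < k) {
      for (l in (j + 1L):k) {
        if (!keep[l]) next
        if (cor(norm[, j], norm[, l]) <= threshold) {
          keep[l] <- FALSE
          removed <- c(removed, colnames(t$values)[l])
          message("dedupe_reversed: dropping '", colnames(t$values)[l],
                  "' (reversed duplicate of '", colnames(t$values)[j], "')")
        }
      }
    }
  }
  out <- scale_table(t$values[, keep, drop = FALSE], provenance = t$provenance)
  attr(out, "removed") <- removed
  out
}

#' Draw a random initial scale
#'
#' 20 independent standard-normal draws, one per canonical residue, then
#' (by default) centered and scaled to unit sample variance so that the
#' scale-optimizer's step size, a fraction of unit variance, means the
#' same thing from iteration zero.
#'
#' @param seed Integer seed; the same seed always yields the same scale.
#' @param name Scale identifier.
#' @param normalize Normalize after drawing (default `TRUE`).
#' @return An `aa_scale`.
#' @export
random_scale <- function(seed, name = paste0("random_", seed),
                         normalize = TRUE) {
  v <- with_seed(seed, rnorm(20L))
  s <- aa_scale(name, structure(v, names = aa_residues()))
  if (normalize) normalize_scale(s) else s
}

# Run code under a local RNG seed without clobbering the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream of sub-seeds from one master seed (32-bit safe).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
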
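#' Construct an omics matrix with tumor/normal group labels
#'
#' Light container for a genes-or-probes x samples numeric matrix carrying the
#' per-column group assignment (`tumor` / `normal`) and an optional pair id for
#' matched tumor/normal designs.
#'
#' @param values numeric matrix with unique rownames (features) and colnames
#'   (samples).
#' @param group character or factor of length `ncol(values)` with levels
#'   `tumor` and `normal`.
#' @param pair optional vector of pair identifiers, one per column; columns
#'   sharing an id are a matched tumor/normal pair.
#' @param type `"expression"` (values must be non-negative) or
#'   `"methylation"` (beta values must lie in \[0, 1\]).
#' @return An object of class `omics_matrix`: the matrix with `group`, `pair`
#'   and `type` attributes.
#' @export
omics_matrix <- function(values, group, pair = NULL,
                         type = c("expression", "methylation")) {
  type <- match.arg(type)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique colnames")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` must have one label per column")
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  finite <- values[is.finite(values)]
  if (type == "methylation" && length(finite) &&
      (min(finite) < 0 || max(finite) > 1))
    stop("methylation beta values must lie in [0, 1]")
  if (type == "expression" && length(finite) && min(finite) < 0)
    stop("expression values must be non-negative")
  if (!is.null(pair) && length(pair) != ncol(values))
    stop("`pair` must have one id per column")
  structure(values, group = group, pair = pair, type = type,
            class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  g <- table(attr(x, "group"))
  cat(sprintf("omics_matrix (%s): %d features x %d samples (%s)\n",
              attr(x, "type"), nrow(x), ncol(x),
              paste(sprintf("%d %s", g, names(g)), collapse = ", ")))
  invisible(x)
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  grp <- attr(x, "group")
  pr <- attr(x, "pair")
  if (!missing(j)) {
    jj <- seq_len(ncol(unclass(x)))
    names(jj) <- colnames(unclass(x))
    jj <- jj[j]
    grp <- grp[jj]
    if (!is.null(pr)) pr <- pr[jj]
  }
  structure(out, group = grp, pair = pr, type = attr(x, "type"),
            class = class(x))
}

#' Tumor/normal group labels of an omics matrix
#' @param x an `omics_matrix`.
#' @return character vector of per-column group labels.
#' @export
groups_of <- function(x) attr(x, "group")

#' Split an omics matrix into tumor and normal submatrices
#' @param x an `omics_matrix`.
#' @return list with plain matrices `tumor` and `normal`.
#' @keywords internal
split_groups <- function(x) {
  g <- groups_of(x)
  list(tumor = unclass(x)[, g == "tumor", drop = FALSE],
       normal = unclass(x)[, g == "normal", drop = FALSE])
}
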
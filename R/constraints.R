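#' Linear flux constraint sets (target / desired polyhedra)
#'
#' A set of linear inequalities \eqn{M r \le rhs} over the reaction rates of
#' a network, used to describe either the target (undesired) flux polyhedron
#' that the cut sets must empty, or the desired flux polyhedron of which at
#' least one element must survive the cuts.  Inputs with \code{">="} or
#' \code{"="} senses are normalized to \code{"<="} rows (an equality becomes
#' two rows), so a single canonical form enters the dualization.
#'
#' @param coeffs numeric matrix (constraints in rows); column names, when
#'   present, are matched against reaction identifiers on binding.
#' @param rhs numeric right-hand sides.
#' @param dir row senses, any of \code{"<=", "=", ">="}; default all
#'   \code{"<="}.
#' @param label free-text label (\code{"target"}, \code{"desired"}, ...).
#' @return An object of class \code{flux_constraints} with all rows in
#'   \code{<=} form.
#' @export
flux_constraints <- function(coeffs, rhs, dir = rep("<=", length(rhs)),
                             label = "target") {
  coeffs <- as.matrix(coeffs)
  storage.mode(coeffs) <- "double"
  stopifnot(nrow(coeffs) == length(rhs), length(dir) == length(rhs))
  bad <- !dir %in% c("<=", "=", ">=")
  if (any(bad)) stop("constraint senses must be '<=', '=' or '>='")
  M <- NULL; b <- NULL
  for (i in seq_along(rhs)) {
    if (dir[i] %in% c("<=", "=")) { M <- rbind(M, coeffs[i, ]); b <- c(b, rhs[i]) }
    if (dir[i] %in% c(">=", "=")) { M <- rbind(M, -coeffs[i, ]); b <- c(b, -rhs[i]) }
  }
  rownames(M) <- NULL
  structure(list(coeffs = M, rhs = as.numeric(b), label = label),
            class = "flux_constraints")
}

#' @export
print.flux_constraints <- function(x, ...) {
  cat(sprintf("flux_constraints '%s': %d row(s) (<= form) over %d column(s)\n",
              x$label, nrow(x$coeffs), ncol(x$coeffs)))
  invisible(x)
}

# Align a constraint set with a network's reaction columns. Accepts either
# matching column count or named columns (subset of reaction ids).
bind_constraints <- function(cs, net) {
  stopifnot(inherits(cs, "flux_constraints"))
  M <- cs$coeffs
  n <- n_rxn(net)
  if (!is.null(colnames(M)) && !identical(colnames(M), net$reaction_ids)) {
    i <- match(colnames(M), net$reaction_ids)
    if (anyNA(i))
      stop("constraint set references unknown reaction(s): ",
           paste(colnames(M)[is.na(i)], collapse = ", "))
    full <- matrix(0, nrow(M), n, dimnames = list(NULL, net$reaction_ids))
    full[, i] <- M
    M <- full
  } else if (ncol(M) != n) {
    stop("dimension mismatch: constraint set has ", ncol(M),
         " columns, network has ", n, " reactions")
  }
  list(coeffs = M, rhs = cs$rhs, label = cs$label)
}

#' Build a constraint set from text lines
#'
#' Mini-grammar, one constraint per line:
#' \code{"coef reaction_id [+ coef reaction_id ...] <= value"} (also
#' \code{>=}, \code{=}).  A bare reaction id means coefficient 1; negative
#' coefficients are written as e.g. \code{-1 R_EX_o2}.
#'
#' @param lines character vector of constraint lines (blank lines and
#'   \code{#} comments ignored).
#' @param label constraint-set label.
#' @return A \code{\link{flux_constraints}} (with named columns; bind to a
#'   network at use time).
#' @export
parse_constraints <- function(lines, label = "target") {
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no constraints found")
  rows <- lapply(lines, function(ln) {
    m <- regexpr("<=|>=|=", ln)
    if (m < 0) stop("no relation in constraint line: '", ln, "'")
    op <- regmatches(ln, m)
    lhs <- trimws(substr(ln, 1, m - 1))
    val <- suppressWarnings(as.numeric(trimws(substr(ln, m + attr(m, "match.length"),
                                                     nchar(ln)))))
    if (is.na(val)) stop("cannot parse right-hand side in: '", ln, "'")
    terms <- trimws(strsplit(lhs, "+", fixed = TRUE)[[1]])
    coefs <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coefs[parts[1]] <- 1
      } else {
        cf <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(cf)) stop("cannot parse term '", tm, "' in: '", ln, "'")
        coefs[paste(parts[-1], collapse = " ")] <- cf
      }
    }
    list(coefs = coefs, op = op, val = val)
  })
  ids <- unique(unlist(lapply(rows, function(r) names(r$coefs))))
  M <- matrix(0, length(rows), length(ids), dimnames = list(NULL, ids))
  for (i in seq_along(rows)) M[i, names(rows[[i]]$coefs)] <- rows[[i]]$coefs
  flux_constraints(M, vapply(rows, `[[`, 0, "val"),
                   vapply(rows, `[[`, "", "op"), label = label)
}

#' Read a constraint file
#'
#' @param path text file in the grammar of \code{\link{parse_constraints}}.
#' @param label constraint-set label.
#' @return A \code{\link{flux_constraints}}.
#' @export
read_constraints <- function(path, label = "target") {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_constraints(readLines(path, warn = FALSE), label = label)
}

#' Validate a target flux polyhedron
#'
#' A target set is only meaningful if the zero flux vector is \emph{not}
#' contained in it (no knockout can ever block the zero flux vector) and if
#' the polyhedron intersected with the steady-state constraints is
#' non-empty (otherwise there is nothing to cut and enumeration returns no
#' cut sets).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param target a \code{\link{flux_constraints}}.
#' @return A list with \code{zero_in_polyhedron}, \code{nonempty} (one LP),
#'   and \code{valid} (\code{TRUE} iff zero vector excluded).
#' @export
validate_target <- function(net, target) {
  cs <- bind_constraints(target, net)
  zero_in <- all(cs$rhs >= -1e-12)
  lpd <- network_lp(net, constraints = target, use_bounds = FALSE)
  feas <- lp_feasible(lpd$mat, lpd$dir, lpd$rhs, lpd$lb, lpd$ub)
  structure(list(zero_in_polyhedron = zero_in,
                 nonempty = isTRUE(feas),
                 valid = !zero_in),
            class = "target_validation")
}

#' @export
print.target_validation <- function(x, ...) {
  cat("target validation:\n",
      sprintf("  zero flux vector in target polyhedron: %s%s\n",
              x$zero_in_polyhedron,
              if (x$zero_in_polyhedron) "  [INVALID target]" else ""),
      sprintf("  target polyhedron non-empty under steady state: %s%s\n",
              x$nonempty, if (!x$nonempty) "  [no cut sets needed]" else ""),
      sep = "")
  invisible(x)
}
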
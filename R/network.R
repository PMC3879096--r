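#' Construct a stoichiometric metabolic network
#'
#' The central container of the package: an \eqn{m \times n} stoichiometric
#' matrix \eqn{N} over \eqn{m} internal metabolites and \eqn{n} reactions,
#' together with reversibility flags, optional flux bounds and per-reaction
#' tags.  Steady-state behaviour is the solution set of \eqn{N r = 0} with
#' \eqn{r_i \ge 0} for irreversible reactions.
#'
#' @param stoich numeric matrix, metabolites in rows, reactions in columns.
#' @param reaction_ids,metabolite_ids unique identifier vectors; defaults
#'   taken from dimnames.
#' @param reversible logical vector, length \code{ncol(stoich)}.
#' @param lb,ub optional per-reaction bounds.  Absent bounds mean
#'   unbounded subject to irreversibility (\code{lb = 0} for irreversible
#'   reactions, \code{-Inf} otherwise; \code{ub = Inf}).
#' @param knockable,exchange,spontaneous logical per-reaction tags.
#'   Exchange and spontaneous reactions default to non-knockable.
#' @return An object of class \code{metabolic_network}.
#' @export
metabolic_network <- function(stoich, reaction_ids = colnames(stoich),
                              metabolite_ids = rownames(stoich),
                              reversible = rep(FALSE, ncol(stoich)),
                              lb = NULL, ub = NULL,
                              knockable = NULL,
                              exchange = rep(FALSE, ncol(stoich)),
                              spontaneous = rep(FALSE, ncol(stoich))) {
  stoich <- as.matrix(stoich)
  storage.mode(stoich) <- "double"
  n <- ncol(stoich); m <- nrow(stoich)
  if (is.null(reaction_ids)) reaction_ids <- sprintf("R%d", seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- sprintf("M%d", seq_len(m))
  reaction_ids <- as.character(reaction_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(reaction_ids) != n)
    stop("length(reaction_ids) must equal ncol(stoich)")
  if (length(metabolite_ids) != m)
    stop("length(metabolite_ids) must equal nrow(stoich)")
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction identifier: ",
         reaction_ids[duplicated(reaction_ids)][1L])
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite identifier: ",
         metabolite_ids[duplicated(metabolite_ids)][1L])
  reversible <- rep_len(as.logical(reversible), n)
  if (is.null(lb)) lb <- ifelse(reversible, -Inf, 0)
  if (is.null(ub)) ub <- rep(Inf, n)
  lb <- rep_len(as.numeric(lb), n); ub <- rep_len(as.numeric(ub), n)
  if (any(!reversible & lb < 0))
    stop("irreversible reactions must have lower_bound >= 0: ",
         paste(reaction_ids[!reversible & lb < 0], collapse = ", "))
  exchange <- rep_len(as.logical(exchange), n)
  spontaneous <- rep_len(as.logical(spontaneous), n)
  if (is.null(knockable)) knockable <- !(exchange | spontaneous)
  knockable <- rep_len(as.logical(knockable), n)
  dimnames(stoich) <- list(metabolite_ids, reaction_ids)
  structure(list(stoich = stoich,
                 reaction_ids = reaction_ids,
                 metabolite_ids = metabolite_ids,
                 reversible = reversible,
                 lb = lb, ub = ub,
                 knockable = knockable,
                 exchange = exchange,
                 spontaneous = spontaneous),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites x %d reactions (%d reversible, %d knockable)\n",
              length(x$metabolite_ids), length(x$reaction_ids),
              sum(x$reversible), sum(x$knockable)))
  invisible(x)
}

n_rxn <- function(net) length(net$reaction_ids)
n_met <- function(net) length(net$metabolite_ids)

rxn_index <- function(net, ids) {
  i <- match(ids, net$reaction_ids)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  i
}

# -- text arrow-notation equation parsing ------------------------------------

parse_equation <- function(eq) {
  # "2 A + B -> C" / "A <-> B" / "-> A" / "B ->"
  rev_arrow <- grepl("<->|<=>", eq)
  pos <- regexpr("<->|<=>|->", eq)
  if (pos < 0) stop("no reaction arrow in equation: '", eq, "'")
  sides <- c(substr(eq, 1L, pos - 1L),
             substr(eq, pos + attr(pos, "match.length"), nchar(eq)))
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(NULL)
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) c(1, parts) else {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("cannot parse equation term: '", tm, "'")
        c(coef, paste(parts[-1], collapse = " "))
      }
    })
    data.frame(met = vapply(out, `[`, "", 2L),
               coef = sign * as.numeric(vapply(out, `[`, "", 1L)))
  }
  res <- rbind(parse_side(sides[1], -1), parse_side(sides[2], +1))
  list(terms = res, reversible = rev_arrow)
}

# -- tabular dialect ---------------------------------------------------------

#' Read a metabolic network from file
#'
#' Two formats are supported.  The tabular dialect is a tab-separated file
#' with header columns \code{reaction_id}, \code{equation} (text arrow
#' notation, e.g. \code{"2 A + B -> C"}), \code{reversible} (0/1), \code{lb},
#' \code{ub}, \code{knockable} (0/1); the last four columns are optional.
#' SBML Level 2/3 (with FBC flux bounds where present) is read through
#' \pkg{xml2}; species marked \code{boundaryCondition="true"} are treated as
#' external and dropped from the stoichiometric matrix.
#'
#' @param path file path.
#' @param format \code{"tabular"} or \code{"sbml"}; guessed from the file
#'   extension by default.
#' @return A \code{\link{metabolic_network}}.
#' @export
read_network <- function(path, format = c("auto", "tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "tabular"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "sbml") read_sbml(path) else read_tabular(path)
}

read_tabular <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  need <- c("reaction_id", "equation")
  if (!all(need %in% names(tab)))
    stop("tabular model needs columns 'reaction_id' and 'equation'; got: ",
         paste(names(tab), collapse = ", "))
  if (anyDuplicated(tab$reaction_id))
    stop("duplicate reaction identifier: ",
         tab$reaction_id[duplicated(tab$reaction_id)][1L])
  parsed <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tryCatch(parse_equation(tab$equation[i]),
                  error = function(e) stop("record '", tab$reaction_id[i],
                                           "': ", conditionMessage(e)))
    p
  })
  mets <- unique(unlist(lapply(parsed, function(p) p$terms$met)))
  S <- matrix(0, length(mets), nrow(tab), dimnames = list(mets, tab$reaction_id))
  for (i in seq_along(parsed)) {
    tm <- parsed[[i]]$terms
    if (!is.null(tm))
      for (k in seq_len(nrow(tm))) S[tm$met[k], i] <- S[tm$met[k], i] + tm$coef[k]
  }
  reversible <- if ("reversible" %in% names(tab)) tab$reversible != 0
                else vapply(parsed, `[[`, TRUE, "reversible")
  # exchange reactions: one side of the arrow empty
  exchange <- vapply(parsed, function(p)
    is.null(p$terms) || all(p$terms$coef > 0) || all(p$terms$coef < 0), TRUE)
  lb <- if ("lb" %in% names(tab)) as.numeric(tab$lb) else NULL
  ub <- if ("ub" %in% names(tab)) as.numeric(tab$ub) else NULL
  knock <- if ("knockable" %in% names(tab)) tab$knockable != 0 else NULL
  metabolic_network(S, reversible = reversible, lb = lb, ub = ub,
                    knockable = knock, exchange = exchange)
}

#' Write a network in the tabular dialect
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_network_tab <- function(net, path) {
  fmt_side <- function(col, sel) {
    if (!any(sel)) return("")
    co <- abs(col[sel])
    paste(ifelse(co == 1, net$metabolite_ids[sel],
                 paste(format(co, trim = TRUE, digits = 12),
                       net$metabolite_ids[sel])),
          collapse = " + ")
  }
  eqs <- vapply(seq_len(n_rxn(net)), function(j) {
    col <- net$stoich[, j]
    paste(fmt_side(col, col < 0), "->", fmt_side(col, col > 0))
  }, "")
  tab <- data.frame(reaction_id = net$reaction_ids, equation = trimws(eqs),
                    reversible = as.integer(net$reversible),
                    lb = net$lb, ub = net$ub,
                    knockable = as.integer(net$knockable))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- SBML --------------------------------------------------------------------

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_bnd <- tolower(xml2::xml_attr(sp, "boundaryCondition")) %in% "true"
  internal <- sp_id[!sp_bnd]
  if (anyDuplicated(sp_id))
    stop("duplicate metabolite identifier: ", sp_id[duplicated(sp_id)][1L])
  # fbc parameters for flux bounds
  par <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                            xml2::xml_attr(par, "id"))
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx) == 0L) stop("SBML format error: no reaction records found")
  rid <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(rid))
    stop("duplicate reaction identifier: ", rid[duplicated(rid)][1L])
  rev <- xml2::xml_attr(rx, "reversible")
  rev <- ifelse(is.na(rev), TRUE, tolower(rev) == "true")  # L2 default: true
  S <- matrix(0, length(internal), length(rx),
              dimnames = list(internal, rid))
  lb <- ifelse(rev, -Inf, 0); ub <- rep(Inf, length(rx))
  exchange <- logical(length(rx))
  for (j in seq_along(rx)) {
    get_refs <- function(tag, sign) {
      refs <- xml2::xml_find_all(
        rx[[j]], sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (length(refs) == 0L) return(NULL)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      data.frame(met = xml2::xml_attr(refs, "species"), coef = sign * st)
    }
    tm <- rbind(get_refs("listOfReactants", -1), get_refs("listOfProducts", +1))
    touched <- FALSE
    if (!is.null(tm)) for (k in seq_len(nrow(tm))) {
      if (tm$met[k] %in% internal) {
        S[tm$met[k], j] <- S[tm$met[k], j] + tm$coef[k]
        touched <- TRUE
      }
    }
    # reactions touching only boundary species (or one-sided) act as exchanges
    n_int <- sum(S[, j] != 0)
    n_tot <- if (is.null(tm)) 0L else nrow(tm)
    exchange[j] <- n_int < n_tot || n_tot <= 1L
    lbref <- xml2::xml_attr(rx[[j]], "lowerFluxBound")
    ubref <- xml2::xml_attr(rx[[j]], "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(parval)) lb[j] <- parval[[lbref]]
    if (!is.na(ubref) && ubref %in% names(parval)) ub[j] <- parval[[ubref]]
    if (touched) NULL
  }
  if (any(!rev & lb < 0)) lb[!rev & lb < 0] <- 0
  metabolic_network(S, reversible = rev, lb = lb, ub = ub, exchange = exchange)
}

# -- reversible splitting ----------------------------------------------------

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Every reversible reaction \code{R} is replaced by \code{R_fwd} (original
#' column) and \code{R_bwd} (negated column), both irreversible.  The
#' returned pairing is needed to forbid spurious two-cycles (a forward and
#' its backward direction active together) during elementary-mode
#' enumeration.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @return A list with elements \code{network} (all-irreversible) and
#'   \code{pairs}, a data frame with columns \code{fwd}, \code{bwd},
#'   \code{orig} (identifiers), empty when nothing was split.
#' @export
split_reversible <- function(net) {
  revi <- which(net$reversible)
  if (length(revi) == 0L)
    return(list(network = net,
                pairs = data.frame(fwd = character(), bwd = character(),
                                   orig = character())))
  ids <- newids <- net$reaction_ids
  newids[revi] <- paste0(ids[revi], "_fwd")
  bwd_ids <- paste0(ids[revi], "_bwd")
  if (any(c(newids[revi], bwd_ids) %in% setdiff(ids, ids[revi])) ||
      anyDuplicated(c(newids, bwd_ids)))
    stop("identifier collision while splitting reversible reactions")
  S <- cbind(net$stoich, -net$stoich[, revi, drop = FALSE])
  colnames(S) <- c(newids, bwd_ids)
  k <- length(revi)
  lb <- c(pmax(net$lb, 0), pmax(-net$ub[revi], 0))
  ub <- c(pmax(net$ub, 0), pmax(-net$lb[revi], 0))
  lb[revi] <- pmax(net$lb[revi], 0)
  ub[revi] <- pmax(net$ub[revi], 0)
  out <- metabolic_network(
    S,
    reversible = rep(FALSE, ncol(S)),
    lb = lb, ub = ub,
    knockable = c(net$knockable, net$knockable[revi]),
    exchange = c(net$exchange, net$exchange[revi]),
    spontaneous = c(net$spontaneous, net$spontaneous[revi]))
  list(network = out,
       pairs = data.frame(fwd = newids[revi], bwd = bwd_ids, orig = ids[revi]))
}

# -- steady-state LP assembly ------------------------------------------------

# Rows N r = 0 plus optional constraint-set rows, with per-reaction bounds.
# fix_zero: reaction ids forced to zero (knockouts). Returns mat/dir/rhs/lb/ub.
network_lp <- function(net, constraints = NULL, fix_zero = character(),
                       use_bounds = TRUE) {
  n <- n_rxn(net)
  mat <- net$stoich
  dir <- rep("=", nrow(mat))
  rhs <- rep(0, nrow(mat))
  if (!is.null(constraints)) {
    cs <- bind_constraints(constraints, net)
    mat <- rbind(mat, cs$coeffs)
    dir <- c(dir, rep("<=", nrow(cs$coeffs)))
    rhs <- c(rhs, cs$rhs)
  }
  if (use_bounds) {
    lb <- ifelse(net$reversible, net$lb, pmax(net$lb, 0))
    ub <- net$ub
  } else {
    # the bare steady-state cone: irreversibility only, no box bounds
    lb <- ifelse(net$reversible, -Inf, 0)
    ub <- rep(Inf, n)
  }
  if (length(fix_zero)) {
    i <- rxn_index(net, fix_zero)
    lb[i] <- 0; ub[i] <- 0
  }
  list(mat = mat, dir = dir, rhs = rhs, lb = lb, ub = ub)
}
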
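# Accuracy evaluation: TP/FN/VP/FP categories and D-rate/SEN/PRE/F1.

#' Categorize one assignment against the truth at a rank
#'
#' Categories at the chosen rank: \strong{TP} when the assignment projects
#' to the same taxon as the truth at that rank (assignments at the rank or
#' any lower rank in the correct clade count); \strong{VP} (species rank
#' only) when the assignment is correct at genus rank but carries no
#' species information; \strong{FP} when the assignment conflicts with the
#' truth's clade; \strong{FN} when the read is unclassified (or the
#' assignment sits above the rank on the truth's own lineage, carrying no
#' wrong information). Unclassified reads whose true taxon is absent from
#' the database (\code{db_taxa}) are \strong{TN}.
#'
#' For example, a read of species A in genus G assigned to G is a TP at
#' genus rank but a VP at species rank; assigned to sibling species B of
#' G it is a TP at genus rank but an FP at species rank.
#'
#' @param assigned Assigned taxid, or \code{NA} for unclassified.
#' @param truth True source taxid.
#' @param level \code{"genus"} or \code{"species"}.
#' @param tree A \code{taxonomy_tree}.
#' @param db_taxa Optional taxids present in the database (for TN
#'   bookkeeping of unclassified reads with absent truth).
#' @return One of \code{"TP"}, \code{"VP"}, \code{"FP"}, \code{"FN"},
#'   \code{"TN"}.
#' @export
categorize_assignment <- function(assigned, truth, level, tree,
                                  db_taxa = NULL) {
  stopifnot(level %in% c("genus", "species"))
  if (is.na(assigned)) {
    if (!is.null(db_taxa)) {
      keep <- any(vapply(db_taxa, function(t)
        truth %in% taxon_lineage(tree, t) || t %in% taxon_lineage(tree, truth),
        logical(1)))
      if (!keep) return("TN")
    }
    return("FN")
  }
  proj_t <- ancestor_at_rank(tree, truth, level)
  if (is.na(proj_t))
    .dk_stop("dktax_unknown_taxid",
             sprintf("truth taxid %d has no ancestor at rank %s", truth, level))
  proj_a <- ancestor_at_rank(tree, assigned, level)
  if (!is.na(proj_a))
    return(if (proj_a == proj_t) "TP" else "FP")
  # assignment sits above the requested rank
  if (level == "species") {
    ga <- ancestor_at_rank(tree, assigned, "genus")
    gt <- ancestor_at_rank(tree, truth, "genus")
    if (!is.na(ga) && !is.na(gt) && ga == gt) return("VP")
  }
  # above genus: on the truth's lineage it asserts nothing wrong -> FN,
  # off the lineage it is an incorrect call -> FP
  if (assigned %in% taxon_lineage(tree, truth)) "FN" else "FP"
}

#' Tally evaluation categories
#'
#' @param categories Character vector of categories from
#'   [categorize_assignment()].
#' @param level The evaluated rank.
#' @return A list of class \code{eval_counts}: \code{level}, \code{TP},
#'   \code{FP}, \code{VP}, \code{FN}, \code{TN}, \code{total}.
#' @export
eval_counts <- function(categories, level) {
  tab <- table(factor(categories, levels = c("TP", "FP", "VP", "FN", "TN")))
  structure(list(level = level, TP = unname(tab["TP"]), FP = unname(tab["FP"]),
                 VP = unname(tab["VP"]), FN = unname(tab["FN"]),
                 TN = unname(tab["TN"]), total = length(categories)),
            class = "eval_counts")
}

#' Classification accuracy metrics
#'
#' Computes, from the category tallies:
#' \itemize{
#'   \item detection rate \code{D_rate = (TP + FP + VP) / total},
#'   \item sensitivity \code{SEN = TP / (TP + FP + VP + FN)},
#'   \item precision \code{PRE = TP / (TP + FP)},
#'   \item \code{F1 = 2 * SEN * PRE / (SEN + PRE)}.
#' }
#' A zero denominator yields 0 for that metric, with the
#' \code{"degenerate"} attribute set to TRUE.
#'
#' @param counts An \code{eval_counts} object.
#' @return Named numeric vector \code{D_rate}, \code{SEN}, \code{PRE},
#'   \code{F1}.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  with(counts, {
    d <- div(TP + FP + VP, total)
    sen <- div(TP, TP + FP + VP + FN)
    pre <- div(TP, TP + FP)
    f1 <- div(2 * sen * pre, sen + pre)
    out <- c(D_rate = d, SEN = sen, PRE = pre, F1 = f1)
    attr(out, "degenerate") <- degenerate
    out
  })
}

#' Score read assignments against truth at a rank
#'
#' @param assignments A \code{read_assignments} data.frame (or any frame
#'   with \code{read_id}, \code{taxid}, \code{status}).
#' @param truth data.frame with \code{read_id} and \code{taxid} (the true
#'   source taxon).
#' @param tree A \code{taxonomy_tree}.
#' @param level \code{"genus"} or \code{"species"}.
#' @param db_taxa Optional database taxids for TN bookkeeping.
#' @return A list of class \code{taxa_eval}: \code{counts}
#'   (\code{eval_counts}) and \code{metrics}.
#' @export
evaluate_assignments <- function(assignments, truth, tree,
                                 level = c("genus", "species"),
                                 db_taxa = NULL) {
  level <- match.arg(level)
  i <- match(assignments$read_id, truth$read_id)
  if (anyNA(i))
    .dk_stop("dktax_format_error", "assignment read_id missing from truth")
  true_tax <- truth$taxid[i]
  assigned <- assignments$taxid
  assigned[assignments$status != "C"] <- NA_integer_
  cats <- vapply(seq_along(assigned), function(j)
    categorize_assignment(assigned[j], true_tax[j], level, tree, db_taxa),
    character(1))
  counts <- eval_counts(cats, level)
  structure(list(counts = counts, metrics = classification_metrics(counts),
                 categories = cats),
            class = "taxa_eval")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("%s-level counts: TP=%d FP=%d VP=%d FN=%d TN=%d (total %d)\n",
              x$level, x$TP, x$FP, x$VP, x$FN, x$TN, x$total))
  invisible(x)
}

#' @export
print.taxa_eval <- function(x, ...) {
  print(x$counts)
  m <- x$metrics
  cat(sprintf("D-rate=%.4f  SEN=%.4f  PRE=%.4f  F1=%.4f\n",
              m["D_rate"], m["SEN"], m["PRE"], m["F1"]))
  invisible(x)
}
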
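#' Tertile membership of a score vector
#'
#' Splits subjects at the empirical 1/3 and 2/3 quantiles of the supplied
#' values. Coding follows the subgroup naming convention: 1 = upper third,
#' 2 = middle, 3 = lower. A value exactly at a cut point goes to the
#' lower-numbered (higher) category.
#'
#' @param values Numeric vector, length >= 3.
#' @return Integer vector of 1/2/3 labels. If the cut points coincide
#'   (degenerate, near-constant input) all subjects land in one category and
#'   a warning is issued.
#' @export
tertile_labels <- function(values) {
  stopifnot(length(values) >= 3)
  q <- stats::quantile(values, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (q[1] == q[2])
    warning("degenerate tertile cut points: values are (near-)constant")
  ifelse(values >= q[2], 1L, ifelse(values >= q[1], 2L, 3L))
}

#' Enumerate the 63 overlapping subgroups
#'
#' Builds the full set of subgroup definitions from total-sample tertiles of
#' (i) each disorder's symptom score and (ii) the total-sample factor scores:
#' \itemize{
#'   \item 27 externalising variants `a(ext)-b(ext)-c`: at least one of the 5
#'     externalising disorders in symptom third `a`, Ext factor score in
#'     third `b`, p score in third `c`;
#'   \item 27 internalising variants, analogously over the 3 internalising
#'     disorders and the Int factor score;
#'   \item 9 thought-disorder variants `a(tht)-X-c`: at least one of OCD,
#'     mania, schizophrenia in third `a` and p score in third `c` (the
#'     revised bifactor model has no thought-disorder factor, so no factor
#'     third applies).
#' }
#' Membership is overlapping: one subject can qualify for several values of
#' the symptom third through different disorders.
#'
#' @param symptoms n x 11 symptom matrix with indicator column names.
#' @param factor_scores n x k matrix of total-sample factor scores containing
#'   columns `p`, `Ext`, `Int` (typically from the revised bifactor fit).
#' @return List of 63 `bfs_subgroup` objects, each with `class`
#'   (`ext`/`int`/`tht`), `symptom_third`, `factor_third` (NA for tht),
#'   `p_third`, `label`, `members` (integer indices) and `n`.
#' @export
enumerate_subgroups <- function(symptoms, factor_scores) {
  symptoms <- as.matrix(symptoms)
  need <- c("p", "Ext", "Int")
  if (!all(need %in% colnames(factor_scores)))
    stop("factor_scores must contain columns p, Ext, Int")
  dom <- disorder_domains()
  sym_t <- apply(symptoms[, psycho_indicators(), drop = FALSE], 2,
                 tertile_labels)
  fac_t <- apply(factor_scores[, need, drop = FALSE], 2, tertile_labels)

  any_in_third <- function(cols, a)
    rowSums(sym_t[, cols, drop = FALSE] == a) > 0

  defs <- list()
  for (cls in c("ext", "int", "tht")) {
    cols <- dom[[cls]]
    fac <- c(ext = "Ext", int = "Int", tht = NA)[[cls]]
    for (a in 1:3) {
      in_a <- any_in_third(cols, a)
      bs <- if (is.na(fac)) NA_integer_ else 1:3
      for (b in bs) {
        in_ab <- if (is.na(b)) in_a else in_a & (fac_t[, fac] == b)
        for (cc in 1:3) {
          members <- which(in_ab & fac_t[, "p"] == cc)
          def <- structure(list(class = cls, symptom_third = a,
                                factor_third = b, p_third = cc,
                                label = NA_character_,
                                members = members,
                                n = length(members)),
                           class = "bfs_subgroup")
          def$label <- format_label(def)
          defs[[def$label]] <- def
        }
      }
    }
  }
  defs
}

#' Format / parse a subgroup label
#'
#' Labels follow the `A(x)-B(x)-C` convention: symptom third and class,
#' factor-score third and class, p-score third; thought-disorder variants
#' have no factor third and show `X`, e.g. `"2(ext)-1(ext)-3"` or
#' `"1(tht)-X-1"`.
#'
#' @param def A `bfs_subgroup` (or any list with `class`, `symptom_third`,
#'   `factor_third`, `p_third`).
#' @return `format_label()` a string; `parse_label()` a list with the four
#'   definition fields.
#' @export
format_label <- function(def) {
  mid <- if (is.na(def$factor_third)) "X" else
    sprintf("%d(%s)", def$factor_third, def$class)
  sprintf("%d(%s)-%s-%d", def$symptom_third, def$class, mid, def$p_third)
}

#' @rdname format_label
#' @param label A label string.
#' @export
parse_label <- function(label) {
  m <- regmatches(label,
    regexec("^([123])\\((ext|int|tht)\\)-(?:([123])\\((ext|int)\\)|X)-([123])$",
            label))[[1]]
  if (!length(m)) stop("unparseable subgroup label: ", label)
  list(class = m[3],
       symptom_third = as.integer(m[2]),
       factor_third = if (m[4] == "") NA_integer_ else as.integer(m[4]),
       p_third = as.integer(m[6]))
}

#' @export
print.bfs_subgroup <- function(x, ...) {
  cat("<bfs_subgroup>", x$label, "n =", x$n, "\n")
  invisible(x)
}

#' Subgroup manifest
#'
#' @param defs List of subgroup definitions from [enumerate_subgroups()].
#' @return Data frame with label, class, thirds and size per subgroup.
#' @export
subgroup_manifest <- function(defs) {
  data.frame(label = vapply(defs, `[[`, "", "label"),
             class = vapply(defs, `[[`, "", "class"),
             symptom_third = vapply(defs, `[[`, 0L, "symptom_third"),
             factor_third = vapply(defs, `[[`, 0L, "factor_third"),
             p_third = vapply(defs, `[[`, 0L, "p_third"),
             n = vapply(defs, `[[`, 0L, "n"),
             row.names = NULL)
}
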
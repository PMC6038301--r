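# Human-readable reaction equation strings.
#
# Grammar:  side ("->" | "<=>") side
#           side := term ("+" term)*
#           term := [coefficient] species_id
# Coefficients are decimal (0.5, 1.625, ...); species ids are bare
# tokens (letters, digits, "_"). Species named on both sides are netted.

#' Parse a reaction equation string
#'
#' `"->"` yields an irreversible reaction (bounds `[0, 1000]`), `"<=>"`
#' a reversible one (`[-1000, 1000]`). A species appearing on both sides
#' is netted to a single signed coefficient; an equation whose every
#' coefficient nets to zero (e.g. `"a <=> a"`) is rejected.
#'
#' @param text Equation string, e.g. `"4 h_p + adp + pi -> 3 h_c + atp + h2o"`.
#' @param id Reaction id for the returned object.
#' @param lb,ub Optional explicit bounds overriding the arrow defaults.
#' @inheritParams reaction
#' @return A `rxn`.
#' @examples
#' parse_equation("nh4 -> nh3 + h_p", id = "Trans_NH4")
#' @export
parse_equation <- function(text, id = "r", lb = NULL, ub = NULL,
                           name = "", subsystem = "", genes = "") {
  arrow <- regexpr("->|<=>", text)
  if (arrow < 0)
    abort(sprintf("parse error in '%s': no '->' or '<=>' arrow found", text))
  arrow_txt <- regmatches(text, arrow)
  reversible <- arrow_txt == "<=>"
  lhs <- substr(text, 1, arrow - 1)
  rhs <- substr(text, arrow + attr(arrow, "match.length"), nchar(text))
  st <- c(parse_side(lhs, -1, text, 0L), parse_side(rhs, +1, text, arrow))
  acc <- tapply(st, names(st), sum)
  acc <- setNames(as.numeric(acc), names(acc))
  acc <- acc[abs(acc) > 0]
  if (!length(acc))
    abort(sprintf("degenerate equation '%s': all coefficients net to zero", text))
  reaction(id, acc, lb = lb, ub = ub, reversible = reversible,
           name = name, subsystem = subsystem, genes = genes)
}

parse_side <- function(side, sign, full, offset) {
  side <- trimws(side)
  if (!nzchar(side)) return(setNames(numeric(0), character(0)))
  if (grepl("^\\+|\\+\\s*\\+|\\+$", side))
    abort(sprintf("parse error in '%s': empty term near column %d", full, offset + 1L))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (term in terms) {
    if (!nzchar(term))
      abort(sprintf("parse error in '%s': empty term near column %d", full, offset + 1L))
    m <- regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?([A-Za-z][A-Za-z0-9_]*)$", term)
    g <- regmatches(term, m)[[1]]
    if (!length(g)) {
      col <- offset + regexpr(term, full, fixed = TRUE)
      abort(sprintf("parse error in '%s': malformed term '%s' near column %d", full, term, max(col, 1L)))
    }
    coef <- if (nzchar(g[2])) as.numeric(trimws(g[2])) else 1
    sp <- g[3]
    out[sp] <- if (sp %in% names(out)) out[[sp]] + sign * coef else sign * coef
  }
  out
}

#' Render a reaction as an equation string
#'
#' Inverse of [parse_equation()]: negative coefficients form the left
#' side, positive the right; the arrow is `"<=>"` when the lower bound
#' is negative.
#'
#' @param rxn A `rxn`.
#' @return A single equation string.
#' @export
render_equation <- function(rxn) {
  st <- rxn$stoich
  fmt <- function(v) {
    paste(vapply(names(v), function(s) {
      cf <- signif(abs(v[[s]]), 12)   # strip LP round-off noise
      if (abs(cf - 1) < 1e-12) s else paste(format(cf, digits = 15, scientific = FALSE), s)
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(st[st < 0])
  rhs <- fmt(st[st > 0])
  arrow <- if (is_reversible(rxn)) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}
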
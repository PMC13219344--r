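# Restricted boolean rule grammar for clinician-editable threshold logic.
# Rules are comparison expressions over named inputs combined with AND / OR /
# NOT (or & | !) and parentheses -- no function calls, no assignment, no
# indexing. Text is parsed with the R parser and then the expression tree is
# validated against this whitelist, so arbitrary code in a config file can
# never execute.

RULE_OPS <- c("&", "|", "!", "&&", "||", ">", "<", ">=", "<=", "==", "!=", "(")

normalize_rule_text <- function(text) {
  t <- gsub("\\bAND\\b", "&", text, ignore.case = TRUE)
  t <- gsub("\\bOR\\b", "|", t, ignore.case = TRUE)
  t <- gsub("\\bNOT\\b", "!", t, ignore.case = TRUE)
  t
}

validate_rule_ast <- function(e, text) {
  if (is.numeric(e) || is.logical(e)) return(character())
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    # signed numeric literals parse as unary +/- calls
    if (op %in% c("-", "+") && length(e) == 2L && is.numeric(e[[2]]))
      return(character())
    if (!op %in% RULE_OPS)
      stop_parse("rule '%s': operator or call '%s' is not allowed", text, op)
    return(unique(unlist(lapply(as.list(e)[-1], validate_rule_ast, text))))
  }
  stop_parse("rule '%s': unsupported element '%s'", text, deparse(e))
}

#' Parse a threshold rule from the restricted boolean grammar
#'
#' @param text rule text, e.g. `"Temp > 38 AND HR > 100"`. Identifiers must
#'   name channels or indicators available in the frames the rule is applied
#'   to; comparisons, `AND`/`OR`/`NOT` (or `&`/`|`/`!`) and parentheses are
#'   the whole grammar.
#' @return An object of class `wf_rule` carrying the validated expression and
#'   the identifiers it references.
#' @examples
#' parse_rule("Temp > 38 AND HR > 100")
#' @export
parse_rule <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop_parse("rule text must be a non-empty string")
  norm <- normalize_rule_text(text)
  exprs <- tryCatch(parse(text = norm, keep.source = FALSE),
                    error = function(e) stop_parse(
                      "rule '%s' does not parse: %s", text,
                      conditionMessage(e)))
  if (length(exprs) != 1L)
    stop_parse("rule '%s' must be a single expression", text)
  e <- exprs[[1]]
  vars <- validate_rule_ast(e, text)
  structure(list(text = text, expr = e, vars = vars), class = "wf_rule")
}

#' @export
print.wf_rule <- function(x, ...) {
  cat(sprintf("<wf_rule> %s  (inputs: %s)\n", x$text,
              paste(x$vars, collapse = ", ")))
  invisible(x)
}

# Evaluate a parsed rule on a named list/environment of scalar values.
eval_rule <- function(rule, values) {
  # the AST is whitelist-validated at parse time, so only comparison and
  # logical operators can be looked up in the base enclosure
  isTRUE(eval(rule$expr, envir = values, enclos = baseenv()))
}
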
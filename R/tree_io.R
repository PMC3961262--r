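# Decision-rule extraction and the round-trip tree text format.

#' Extract decision rules from a tree
#'
#' One rule per leaf, in depth-first order with branch values sorted: a
#' conjunction of `attribute = value` tests, the leaf's predicted class,
#' and its case/control counts.  The rules are mutually exclusive and
#' jointly exhaustive over the training data.
#'
#' @param tree an `id3_node`.
#' @return object of class `id3_rules`: list of rules, each with
#'   `conditions` (named character vector), `predicted_class`, `cases`,
#'   `controls`.
#' @export
extract_rules <- function(tree) {
  rules <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      rules[[length(rules) + 1]] <<- list(conditions = conds,
                                          predicted_class = node$predicted_class,
                                          cases = unname(node$counts[["case"]]),
                                          controls = unname(node$counts[["control"]]))
      return(invisible())
    }
    for (v in names(node$branches)) {
      walk(node$branches[[v]], c(conds, stats::setNames(v, node$split_attribute)))
    }
  }
  walk(tree, character(0))
  structure(rules, class = "id3_rules")
}

rule_text <- function(rule) {
  cond <- if (length(rule$conditions) == 0) "TRUE" else {
    paste(names(rule$conditions), "=", rule$conditions, collapse = " & ")
  }
  sprintf("%s -> %s (%d/%d)", cond, rule$predicted_class, rule$cases, rule$controls)
}

#' @export
print.id3_rules <- function(x, ...) {
  cat(sprintf("%d decision rules:\n", length(x)))
  for (r in x) cat(" ", rule_text(r), "\n")
  invisible(x)
}

#' @export
as.data.frame.id3_rules <- function(x, ...) {
  data.frame(
    condition = vapply(x, function(r) {
      if (length(r$conditions) == 0) "TRUE"
      else paste(names(r$conditions), "=", r$conditions, collapse = " & ")
    }, ""),
    predicted_class = vapply(x, `[[`, "", "predicted_class"),
    cases = vapply(x, `[[`, 0, "cases"),
    controls = vapply(x, `[[`, 0, "controls"),
    stringsAsFactors = FALSE)
}

#' Write decision rules as TSV
#' @param rules an `id3_rules` object.
#' @param path output path.
#' @export
write_rules_tsv <- function(rules, path) {
  utils::write.table(as.data.frame(rules), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a tree as indented text
#'
#' One branch per line (`attribute = value`), two-space indentation per
#' level, leaves annotated `-> class (cases/controls)`; a single-leaf tree
#' is one `-> class (c/c)` line.  [parse_tree_text()] restores an
#' identical tree, and export -> parse -> export is byte-identical.
#'
#' @param tree an `id3_node`.
#' @return a single string.
#' @export
export_tree_text <- function(tree) {
  lines <- character(0)
  emit <- function(node, prefix, depth) {
    pad <- strrep("  ", depth)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf("%s%s-> %s (%d/%d)", pad, prefix,
                                 node$predicted_class,
                                 node$counts[["case"]], node$counts[["control"]]))
      return(invisible())
    }
    if (nzchar(prefix)) {
      lines <<- c(lines, paste0(pad, trimws(prefix)))
      depth <- depth + 1
    }
    for (v in names(node$branches)) {
      child <- node$branches[[v]]
      lab <- sprintf("%s = %s ", node$split_attribute, v)
      if (child$type == "leaf") emit(child, lab, depth)
      else emit(child, lab, depth)
    }
  }
  emit(tree, "", 0)
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse the tree text format back into a tree
#'
#' Inverse of [export_tree_text()]; internal-node class counts are
#' reconstructed as the sum of their leaves (every training subject
#' reaches exactly one leaf, so the sums are exact).
#'
#' @param text string or character vector of lines.
#' @return an `id3_node`.
#' @export
parse_tree_text <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(lines)]
  depth <- nchar(sub("[^ ].*$", "", lines)) / 2
  leaf_re <- "-> (case|control) \\((\\d+)/(\\d+)\\)$"
  parse_block <- function(from, to, level) {
    first <- lines[from]
    if (grepl(paste0("^ *", leaf_re), first) && !grepl(" = ", first)) {
      m <- regmatches(first, regexec(leaf_re, first))[[1]]
      return(new_leaf(c(case = as.integer(m[3]), control = as.integer(m[4]))))
    }
    idx <- seq(from, to)
    tops <- idx[depth[idx] == level]
    branches <- list()
    attr_name <- NULL
    for (k in seq_along(tops)) {
      start <- tops[k]
      end <- if (k < length(tops)) tops[k + 1] - 1 else to
      line <- trimws(lines[start])
      m <- regmatches(line, regexec("^(.*?) = (.*?) (->.*)?$", line))[[1]]
      if (length(m) == 0) {
        m <- regmatches(line, regexec("^(.*?) = (.*)$", line))[[1]]
        m <- c(m, "")
      }
      attr_name <- m[2]
      value <- m[3]
      if (nzchar(m[4])) {
        lm <- regmatches(line, regexec(leaf_re, line))[[1]]
        branches[[value]] <- new_leaf(c(case = as.integer(lm[3]),
                                        control = as.integer(lm[4])))
      } else {
        branches[[value]] <- parse_block(start + 1, end, level + 1)
      }
    }
    counts_m <- vapply(branches, `[[`, c(case = 0, control = 0), "counts")
    structure(list(type = "split", split_attribute = attr_name,
                   weighted_score = NA_real_, score = NULL,
                   counts = c(case = sum(counts_m["case", ]),
                              control = sum(counts_m["control", ])),
                   branches = branches[order(names(branches))]),
              class = "id3_node")
  }
  parse_block(1, length(lines), 0)
}

#' Structural equality of two trees
#'
#' Compares split attributes, branch values, and leaf class counts
#' recursively; node scores are ignored (they are not part of the text
#' format).
#'
#' @param a,b `id3_node` trees.
#' @return logical.
#' @export
tree_equal <- function(a, b) {
  if (a$type != b$type) return(FALSE)
  if (a$type == "leaf") {
    return(all(a$counts == b$counts) && a$predicted_class == b$predicted_class)
  }
  if (a$split_attribute != b$split_attribute) return(FALSE)
  if (!identical(names(a$branches), names(b$branches))) return(FALSE)
  all(vapply(names(a$branches),
             function(v) tree_equal(a$branches[[v]], b$branches[[v]]), TRUE))
}
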
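# Generic decision-tree machinery. Costs attach to nodes as increments summed
# along a path; the two evaluators (recursive roll-back, exhaustive path
# enumeration) are deliberately independent implementations so each can serve
# as the other's oracle.

#' Decision-tree nodes
#'
#' A node is one of three kinds. A *chance* node resolves among its branches
#' at random with the stated probabilities (which must sum to 1 within
#' `1e-9`); a *decision* node follows the single branch marked as chosen (the
#' package compares fixed strategies, it never optimizes a policy); a
#' *terminal* node ends the path. Every node carries an incremental cost
#' incurred on entering it.
#'
#' @param label Short label used in path tables and trajectories.
#' @param cost Incremental cost (>= 0) incurred on entering the node.
#' @param branches List of branches built with `branch()`.
#' @param tags Character vector of semantic tags (`"fnac"`, `"surgery"`,
#'   `"revision"`, `"malignant"`, `"follow_up"`) used to derive trajectory
#'   flags.
#' @param chosen For decision nodes, index of the branch that the modeled
#'   strategy takes.
#' @param prob Branch probability (ignored for decision-node branches).
#' @param node Child node.
#' @return A `milan_node` (or, for `branch()`, a branch list).
#' @name tree_nodes
NULL

#' @rdname tree_nodes
#' @export
branch <- function(prob, node) {
  list(prob = prob, node = node)
}

#' @rdname tree_nodes
#' @export
chance_node <- function(label, cost = 0, branches = list(),
                        tags = character()) {
  structure(list(kind = "chance", label = label, cost = cost,
                 branches = branches, tags = tags, chosen = NA_integer_),
            class = "milan_node")
}

#' @rdname tree_nodes
#' @export
decision_node <- function(label, cost = 0, branches = list(), chosen = 1L,
                          tags = character()) {
  structure(list(kind = "decision", label = label, cost = cost,
                 branches = branches, tags = tags,
                 chosen = as.integer(chosen)),
            class = "milan_node")
}

#' @rdname tree_nodes
#' @export
terminal_node <- function(label, cost = 0, tags = character()) {
  structure(list(kind = "terminal", label = label, cost = cost,
                 branches = list(), tags = tags, chosen = NA_integer_),
            class = "milan_node")
}

#' Wrap a root node as a decision tree with metadata
#'
#' @param root A `milan_node`.
#' @param currency `"USD"` or `"EUR"`.
#' @param model_id,arm,iva_surgery_rate Metadata describing which model and
#'   strategy arm the tree encodes; `arm` is `"upfront_surgery"` or
#'   `"fnac_first"` for the built-in arms.
#' @return An object of class `decision_tree`.
#' @export
decision_tree <- function(root, currency, model_id = NA_character_,
                          arm = NA_character_, iva_surgery_rate = NA_real_) {
  stopifnot(inherits(root, "milan_node"))
  currency <- match.arg(currency, c("USD", "EUR"))
  structure(list(root = root, currency = currency, model_id = model_id,
                 arm = arm, iva_surgery_rate = iva_surgery_rate),
            class = "decision_tree")
}

as_root <- function(tree) {
  if (inherits(tree, "decision_tree")) tree$root
  else if (inherits(tree, "milan_node")) tree
  else stop("expected a decision_tree or milan_node", call. = FALSE)
}

PROB_TOL <- 1e-9

#' Structural validation of a decision tree
#'
#' Walks the whole tree and reports every violated invariant with the path of
#' the offending node: negative incremental costs, chance-branch probabilities
#' outside `[0, 1]` or not summing to 1 within `1e-9`, terminal nodes with
#' branches, internal nodes without branches, and decision nodes whose chosen
#' branch is missing or out of range.
#'
#' @param tree A `decision_tree` or bare `milan_node`.
#' @return Character vector of violation messages; empty iff the tree is
#'   valid.
#' @export
validate_tree <- function(tree) {
  problems <- character()
  walk <- function(node, path) {
    here <- paste(path, collapse = " > ")
    if (!is.finite(node$cost) || node$cost < 0) {
      problems <<- c(problems,
                     sprintf("[%s] incremental_cost %s is not a finite number >= 0",
                             here, format(node$cost)))
    }
    nb <- length(node$branches)
    if (node$kind == "terminal") {
      if (nb > 0) {
        problems <<- c(problems,
                       sprintf("[%s] terminal node has %d branches", here, nb))
      }
      return(invisible())
    }
    if (nb == 0) {
      problems <<- c(problems,
                     sprintf("[%s] %s node has no branches", here, node$kind))
      return(invisible())
    }
    if (node$kind == "chance") {
      p <- vapply(node$branches, `[[`, numeric(1), "prob")
      bad <- which(!is.finite(p) | p < 0 | p > 1)
      for (i in bad) {
        problems <<- c(problems,
                       sprintf("[%s] branch %d probability %s outside [0, 1]",
                               here, i, format(p[i])))
      }
      if (all(is.finite(p)) && abs(sum(p) - 1) > PROB_TOL) {
        problems <<- c(problems,
                       sprintf("[%s] branch probabilities sum to %.10g, not 1",
                               here, sum(p)))
      }
    }
    if (node$kind == "decision" &&
        (is.na(node$chosen) || node$chosen < 1 || node$chosen > nb)) {
      problems <<- c(problems,
                     sprintf("[%s] decision node chosen branch %s invalid",
                             here, format(node$chosen)))
    }
    for (i in seq_len(nb)) {
      walk(node$branches[[i]]$node, c(path, node$branches[[i]]$node$label))
    }
  }
  root <- as_root(tree)
  walk(root, root$label)
  problems
}

stop_if_invalid <- function(tree) {
  problems <- validate_tree(tree)
  if (length(problems)) {
    stop("invalid decision tree:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(tree)
}

#' Exact expected cost by recursive roll-back
#'
#' Evaluates \eqn{E[\mathrm{cost}]} as the node's incremental cost plus the
#' probability-weighted expectation of its branches (the chosen branch for a
#' decision node). Deterministic and exact; the tree is validated first and
#' rejected if structurally invalid.
#'
#' @param tree A `decision_tree` or `milan_node`.
#' @param validate Set `FALSE` to skip re-validation (internal reuse).
#' @return Expected total path cost in the tree's currency.
#' @seealso [enumerate_paths()] for the independent path-enumeration oracle.
#' @export
expected_cost <- function(tree, validate = TRUE) {
  if (validate) stop_if_invalid(tree)
  rollback <- function(node) {
    value <- node$cost
    if (node$kind == "terminal") return(value)
    if (node$kind == "decision") {
      return(value + rollback(node$branches[[node$chosen]]$node))
    }
    kids <- vapply(node$branches,
                   function(b) b$prob * rollback(b$node), numeric(1))
    value + sum(kids)
  }
  rollback(as_root(tree))
}

#' Exhaustive enumeration of root-to-terminal paths
#'
#' Lists every path with positive probability, its probability (product of
#' branch probabilities along the way, decision nodes contributing their
#' chosen branch with probability 1) and its total cost (sum of incremental
#' costs of visited nodes). Serves as the brute-force oracle for
#' [expected_cost()]: `sum(probability * cost)` over the rows equals the
#' roll-back value.
#'
#' @param tree A `decision_tree` or `milan_node`.
#' @param sep Separator used to collapse node labels into the `path` column.
#' @return Data frame with columns `path`, `probability`, `cost`.
#' @export
enumerate_paths <- function(tree, sep = " -> ") {
  stop_if_invalid(tree)
  rows <- list()
  descend <- function(node, labels, prob, cost) {
    labels <- c(labels, node$label)
    cost <- cost + node$cost
    if (node$kind == "terminal") {
      rows[[length(rows) + 1L]] <<-
        list(path = paste(labels, collapse = sep),
             probability = prob, cost = cost)
      return(invisible())
    }
    if (node$kind == "decision") {
      descend(node$branches[[node$chosen]]$node, labels, prob, cost)
      return(invisible())
    }
    for (b in node$branches) {
      if (b$prob > 0) descend(b$node, labels, prob * b$prob, cost)
    }
  }
  descend(as_root(tree), character(), 1, 0)
  data.frame(path = vapply(rows, `[[`, character(1), "path"),
             probability = vapply(rows, `[[`, numeric(1), "probability"),
             cost = vapply(rows, `[[`, numeric(1), "cost"))
}

#' Transform every incremental cost in a tree
#'
#' Applies `f` to the incremental cost of every node, preserving structure and
#' probabilities. Used for linearity checks and cost-sensitivity sweeps.
#'
#' @param tree A `decision_tree` or `milan_node`.
#' @param f Function from one cost to one cost.
#' @return Object of the same class as `tree`.
#' @export
map_tree_costs <- function(tree, f) {
  recurse <- function(node) {
    node$cost <- f(node$cost)
    node$branches <- lapply(node$branches, function(b) {
      b$node <- recurse(b$node)
      b
    })
    node
  }
  if (inherits(tree, "decision_tree")) {
    tree$root <- recurse(tree$root)
    tree
  } else {
    recurse(as_root(tree))
  }
}

#' Plain-text and JSON views of a tree
#'
#' `tree_as_text()` renders an indented outline (label, kind, cost, branch
#' probabilities); `tree_as_json()` returns a JSON string of the nested node
#' structure for diffing or archiving.
#'
#' @param tree A `decision_tree` or `milan_node`.
#' @return A character scalar.
#' @name tree_export
NULL

#' @rdname tree_export
#' @export
tree_as_text <- function(tree) {
  lines <- character()
  show <- function(node, depth, prefix) {
    pad <- strrep("  ", depth)
    cost <- if (node$cost != 0) sprintf(" +%.2f", node$cost) else ""
    lines <<- c(lines, sprintf("%s%s%s [%s]%s", pad, prefix, node$label,
                               node$kind, cost))
    for (i in seq_along(node$branches)) {
      b <- node$branches[[i]]
      tag <- if (node$kind == "decision") {
        if (identical(i, as.integer(node$chosen))) "(chosen) " else "(not taken) "
      } else {
        sprintf("p=%.4g ", b$prob)
      }
      show(b$node, depth + 1, tag)
    }
  }
  show(as_root(tree), 0, "")
  paste(lines, collapse = "\n")
}

#' @rdname tree_export
#' @export
tree_as_json <- function(tree) {
  strip <- function(node) {
    list(kind = node$kind, label = node$label, cost = node$cost,
         tags = as.list(node$tags),
         chosen = if (!is.na(node$chosen)) node$chosen,
         branches = lapply(node$branches, function(b) {
           list(prob = b$prob, node = strip(b$node))
         }))
  }
  as.character(jsonlite::toJSON(strip(as_root(tree)), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("Decision tree: model %s, arm %s (%s)",
              x$model_id, x$arm, x$currency))
  if (!is.na(x$iva_surgery_rate)) {
    cat(sprintf(", IVa surgery rate %.2g", x$iva_surgery_rate))
  }
  cat("\n")
  cat(tree_as_text(x), "\n")
  invisible(x)
}
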
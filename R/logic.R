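#' Strand-displacement logic gate
#'
#' One gate of a molecular logic circuit. `YES` and `NOT` take a single
#' input; `OR`, `AND` and `ANDNOT` take two. `ANDNOT` inputs are ordered:
#' the first is asserted, the second inverted (ON iff input1 AND NOT
#' input2). Inputs reference marker names or the labels of upstream gates.
#'
#' @param kind One of `"YES"`, `"NOT"`, `"OR"`, `"AND"`, `"ANDNOT"`.
#' @param inputs Character vector of 1 or 2 source references.
#' @param label Gate label (unique within a circuit).
#' @return An object of class `logic_gate`.
#' @export
logic_gate <- function(kind, inputs, label = NULL) {
  kind <- toupper(kind)
  kind <- sub("^AND-NOT$", "ANDNOT", kind)
  if (!kind %in% c("YES", "NOT", "OR", "AND", "ANDNOT")) {
    stop("unknown gate kind '", kind, "'")
  }
  arity <- if (kind %in% c("YES", "NOT")) 1L else 2L
  if (length(inputs) != arity) {
    stop(kind, " gate takes ", arity, " input(s), got ", length(inputs))
  }
  structure(list(kind = kind, inputs = as.character(inputs), label = label),
            class = "logic_gate")
}

#' Molecular logic circuit
#'
#' A directed acyclic graph of [logic_gate()]s over named marker inputs.
#' Gates may be given in any order; the constructor resolves references,
#' infers the input marker set (references that match no gate label),
#' verifies acyclicity and stores a topological evaluation order.
#'
#' @param gates List of [logic_gate()]s. Unlabelled gates are labelled
#'   `g1, g2, ...` in list order.
#' @param outputs Labels of the output gates; defaults to gates no other
#'   gate consumes.
#' @return An object of class `logic_circuit` with elements `gates`,
#'   `inputs` (marker names), `outputs` and `order` (topological).
#' @examples
#' circ <- logic_circuit(list(
#'   logic_gate("OR", c("KRT19", "VIM"), "or1"),
#'   logic_gate("ANDNOT", c("or1", "PTPRC"), "out")
#' ))
#' @export
logic_circuit <- function(gates, outputs = NULL) {
  if (length(gates) == 0L || !all(vapply(gates, inherits, logical(1), "logic_gate"))) {
    stop("'gates' must be a non-empty list of logic_gate objects")
  }
  for (i in seq_along(gates)) {
    if (is.null(gates[[i]]$label)) gates[[i]]$label <- paste0("g", i)
  }
  labels <- vapply(gates, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate gate labels")
  names(gates) <- labels
  all_inputs <- unique(unlist(lapply(gates, `[[`, "inputs")))
  markers <- setdiff(all_inputs, labels)
  # topological sort over gate-to-gate edges (Kahn)
  order <- character(0)
  ready <- labels[vapply(gates, function(g) !any(g$inputs %in% labels), logical(1))]
  remaining <- setdiff(labels, ready)
  resolved <- character(0)
  queue <- ready
  while (length(queue)) {
    g <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, g)
    resolved <- c(resolved, g)
    now_ready <- remaining[vapply(gates[remaining], function(gg) {
      deps <- intersect(gg$inputs, labels)
      all(deps %in% resolved)
    }, logical(1))]
    queue <- c(queue, now_ready)
    remaining <- setdiff(remaining, now_ready)
  }
  if (length(remaining)) {
    stop("circuit contains a cycle involving: ", paste(remaining, collapse = ", "))
  }
  if (is.null(outputs)) {
    consumed <- unique(unlist(lapply(gates, `[[`, "inputs")))
    outputs <- setdiff(labels, consumed)
    if (length(outputs) == 0L) outputs <- order[length(order)]
  } else if (!all(outputs %in% labels)) {
    stop("unknown output gate(s): ",
         paste(setdiff(outputs, labels), collapse = ", "))
  }
  structure(list(gates = gates, inputs = sort(markers), outputs = outputs,
                 order = order),
            class = "logic_circuit")
}

#' @export
print.logic_circuit <- function(x, ...) {
  cat("Logic circuit:", length(x$gates), "gate(s) over inputs",
      paste(x$inputs, collapse = ", "), "\n")
  for (g in x$gates[x$order]) {
    cat(sprintf("  %s = %s(%s)%s\n", g$label, g$kind,
                paste(g$inputs, collapse = ", "),
                if (g$label %in% x$outputs) "  [output]" else ""))
  }
  invisible(x)
}

#' Evaluate a circuit on a Boolean marker assignment
#'
#' Gate semantics: `YES(x) = x`, `NOT(x) = !x`, `OR(x,y) = x | y`,
#' `AND(x,y) = x & y`, `ANDNOT(x,y) = x & !y`, evaluated in topological
#' order.
#'
#' @param circuit A [logic_circuit()].
#' @param assignment Named logical/0-1 vector covering every input marker.
#' @return Named logical vector of output-gate states.
#' @examples
#' circ <- parse_logic_expression("(KRT19 OR VIM) AND-NOT PTPRC")
#' eval_boolean(circ, c(KRT19 = 1, VIM = 0, PTPRC = 0))
#' @export
eval_boolean <- function(circuit, assignment) {
  stopifnot(inherits(circuit, "logic_circuit"))
  missing <- setdiff(circuit$inputs, names(assignment))
  if (length(missing)) {
    stop("assignment is missing marker(s): ", paste(missing, collapse = ", "))
  }
  vals <- as.logical(assignment)
  names(vals) <- names(assignment)
  state <- as.list(vals)
  for (lab in circuit$order) {
    g <- circuit$gates[[lab]]
    x <- unname(unlist(state[g$inputs]))
    state[[lab]] <- switch(g$kind,
      YES = x[1L],
      NOT = !x[1L],
      OR = x[1L] || x[2L],
      AND = x[1L] && x[2L],
      ANDNOT = x[1L] && !x[2L]
    )
  }
  unlist(state[circuit$outputs])
}

#' Signal-level parameters for strand-displacement gates
#'
#' Equilibrium-level model of the gate chemistry: a transducer emits
#' `on_level` of output strand when its LAMP input is present and `leak`
#' when absent; the AND gate's threshold strand sequesters `and_threshold`
#' worth of output; a reporter reads ON above `detect_cutoff`. Defaults
#' (1.0 / 0.05 / 1.1 / 0.5) are chosen so the Boolean semantics hold with
#' margin: the threshold strand exceeds one active transducer plus the
#' other's leak (1.05) yet leaves two-level cascades above the cutoff.
#' Measured ON/OFF ratios of the wet chemistry are not fitting targets.
#'
#' @param on_level Transducer output when its input is present.
#' @param leak Output when the input is absent (0 <= leak < on_level).
#' @param and_threshold Output sequestered by the AND gate
#'   (leak < and_threshold < 2 * on_level - leak).
#' @param detect_cutoff Fluorescence level counted as ON
#'   (leak < detect_cutoff < on_level).
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(on_level = 1.0, leak = 0.05, and_threshold = 1.1,
                          detect_cutoff = 0.5) {
  if (!(0 <= leak && leak < and_threshold &&
        and_threshold < 2 * on_level - leak)) {
    stop("require 0 <= leak < and_threshold < 2*on_level - leak")
  }
  if (!(leak < detect_cutoff && detect_cutoff < on_level)) {
    stop("require leak < detect_cutoff < on_level")
  }
  structure(list(on_level = on_level, leak = leak,
                 and_threshold = and_threshold,
                 detect_cutoff = detect_cutoff),
            class = "signal_params")
}

#' Evaluate a circuit at signal level
#'
#' Propagates equilibrium output-strand levels instead of Booleans: a
#' marker input enters through its transducer (`on_level` if present, else
#' `leak`); `OR` sums its branches; `AND` subtracts the threshold strand
#' (`max(0, sum - and_threshold)`); `NOT` inverts (`on_level - level`,
#' floored at 0); `ANDNOT` is `max(0, asserted - inverted)`. Every gate
#' output saturates at `on_level` (a fluorogenic reporter cannot exceed its
#' fully-displaced signal). ON/OFF calls compare the level to
#' `detect_cutoff`.
#'
#' Levels attenuate through deep cascades; with the default parameters the
#' calls agree with [eval_boolean()] on single gates and two-level circuits
#' such as `(KRT19 OR VIM) AND-NOT PTPRC`.
#'
#' @param circuit A [logic_circuit()].
#' @param assignment Named logical/0-1 marker assignment.
#' @param params A [signal_params()].
#' @return A list with `levels` (all gate levels), `output_levels` and
#'   `calls` (logical, per output gate).
#' @export
eval_signal <- function(circuit, assignment, params = signal_params()) {
  stopifnot(inherits(circuit, "logic_circuit"), inherits(params, "signal_params"))
  missing <- setdiff(circuit$inputs, names(assignment))
  if (length(missing)) {
    stop("assignment is missing marker(s): ", paste(missing, collapse = ", "))
  }
  transduce <- function(present) if (present) params$on_level else params$leak
  level <- list()
  for (m in circuit$inputs) level[[m]] <- transduce(as.logical(assignment[[m]]))
  clamp <- function(x) min(params$on_level, max(0, x))
  for (lab in circuit$order) {
    g <- circuit$gates[[lab]]
    x <- unname(unlist(level[g$inputs]))
    level[[lab]] <- switch(g$kind,
      YES = clamp(x[1L]),
      NOT = clamp(params$on_level - x[1L]),
      OR = clamp(x[1L] + x[2L]),
      AND = clamp(x[1L] + x[2L] - params$and_threshold),
      ANDNOT = clamp(x[1L] - x[2L])
    )
  }
  out <- unlist(level[circuit$outputs])
  list(levels = unlist(level[circuit$order]),
       output_levels = out,
       calls = out > params$detect_cutoff)
}

#' Exhaustive truth table of a circuit
#'
#' Enumerates all `2^k` assignments of the circuit's `k` input markers
#' (inputs counting in binary, first marker as the most significant bit)
#' and evaluates the outputs, optionally at signal level too.
#'
#' @param circuit A [logic_circuit()] with at most 20 inputs.
#' @param signal If `TRUE`, also evaluate [eval_signal()] and report levels
#'   and signal calls.
#' @param params Signal parameters (used when `signal = TRUE`).
#' @return A data.frame with one column per input marker (0/1), one
#'   `out_<gate>` column per output, and when `signal = TRUE` matching
#'   `level_<gate>` and `call_<gate>` columns.
#' @examples
#' truth_table(parse_logic_expression("A AND B"))
#' @export
truth_table <- function(circuit, signal = FALSE, params = signal_params()) {
  stopifnot(inherits(circuit, "logic_circuit"))
  k <- length(circuit$inputs)
  if (k > 20L) stop("truth table limited to 20 inputs (", k, " given)")
  n <- 2L^k
  tab <- data.frame(row.names = seq_len(n))
  bits <- matrix(0L, n, k, dimnames = list(NULL, circuit$inputs))
  for (j in seq_len(k)) {
    bits[, j] <- (seq_len(n) - 1L) %/% 2L^(k - j) %% 2L
  }
  for (m in circuit$inputs) tab[[m]] <- bits[, m]
  for (g in circuit$outputs) tab[[paste0("out_", g)]] <- NA
  if (signal) {
    for (g in circuit$outputs) {
      tab[[paste0("level_", g)]] <- NA_real_
      tab[[paste0("call_", g)]] <- NA
    }
  }
  for (i in seq_len(n)) {
    a <- stats::setNames(bits[i, ], circuit$inputs)  # 1-col subset drops names
    b <- eval_boolean(circuit, a)
    for (g in circuit$outputs) tab[i, paste0("out_", g)] <- b[[g]]
    if (signal) {
      s <- eval_signal(circuit, a, params)
      for (g in circuit$outputs) {
        tab[i, paste0("level_", g)] <- s$output_levels[[g]]
        tab[i, paste0("call_", g)] <- s$calls[[g]]
      }
    }
  }
  tab
}

## --- expression parser -----------------------------------------------------
## Grammar (AND/AND-NOT bind tighter than OR; NOT/YES are prefix):
##   expr    := andterm (OR andterm)*
##   andterm := unary ((AND | AND-NOT) unary)*
##   unary   := NOT unary | YES unary | atom
##   atom    := MARKER | '(' expr ')'

tokenize_logic <- function(text) {
  pat <- "AND-NOT|ANDNOT|AND|OR|NOT|YES|[A-Za-z_][A-Za-z0-9_]*|\\(|\\)|\\S"
  m <- gregexpr(pat, text)[[1L]]
  if (m[1L] == -1L) stop("empty logic expression")
  toks <- regmatches(text, gregexpr(pat, text))[[1L]]
  data.frame(token = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Parse a Boolean expression into a logic circuit
#'
#' Accepts marker names, parentheses and the operators `OR`, `AND`,
#' `AND-NOT`, `NOT` and `YES` (prefix). `AND` and `AND-NOT` bind tighter
#' than `OR`; binary operators are left-associative. A bare marker is
#' wrapped in a `YES` gate. Syntax errors report the character position.
#'
#' @param text Expression string, e.g. `"(KRT19 OR VIM) AND-NOT PTPRC"`.
#' @return A [logic_circuit()].
#' @examples
#' circ <- parse_logic_expression("(KRT19 OR VIM) AND-NOT PTPRC")
#' truth_table(circ)
#' @export
parse_logic_expression <- function(text) {
  toks <- tokenize_logic(text)
  i <- 1L
  gates <- list()
  peek <- function() if (i <= nrow(toks)) toks$token[i] else NA_character_
  advance <- function() {
    t <- peek()
    i <<- i + 1L
    t
  }
  fail <- function(msg) {
    pos <- if (i <= nrow(toks)) toks$pos[i] else nchar(text) + 1L
    stop("logic syntax error at position ", pos, ": ", msg)
  }
  new_gate <- function(kind, inputs) {
    force(inputs)   # sub-parses must register their gates before we label
    lab <- paste0("g", length(gates) + 1L)
    gates[[lab]] <<- logic_gate(kind, inputs, lab)
    lab
  }
  is_keyword <- function(t) t %in% c("AND", "OR", "NOT", "YES", "AND-NOT",
                                     "ANDNOT", "(", ")")
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (t == "(") {
      advance()
      ref <- parse_expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(ref)
    }
    if (is_keyword(t)) fail(paste0("unexpected '", t, "'"))
    advance()
    t
  }
  parse_unary <- function() {
    t <- peek()
    if (identical(t, "NOT")) {
      advance()
      return(new_gate("NOT", parse_unary()))
    }
    if (identical(t, "YES")) {
      advance()
      return(new_gate("YES", parse_unary()))
    }
    parse_atom()
  }
  parse_andterm <- function() {
    left <- parse_unary()
    repeat {
      t <- peek()
      if (identical(t, "AND")) {
        advance()
        left <- new_gate("AND", c(left, parse_unary()))
      } else if (identical(t, "AND-NOT") || identical(t, "ANDNOT")) {
        advance()
        left <- new_gate("ANDNOT", c(left, parse_unary()))
      } else {
        break
      }
    }
    left
  }
  parse_expr <- function() {
    left <- parse_andterm()
    while (identical(peek(), "OR")) {
      advance()
      left <- new_gate("OR", c(left, parse_andterm()))
    }
    left
  }
  root <- parse_expr()
  if (i <= nrow(toks)) fail(paste0("trailing input '", peek(), "'"))
  if (length(gates) == 0L || !root %in% names(gates)) {
    root <- new_gate("YES", root)   # bare marker
  }
  logic_circuit(unname(gates), outputs = root)
}
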
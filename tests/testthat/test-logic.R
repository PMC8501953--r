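# Reference recursive evaluator for random differential tests: ASTs are
# nested lists (list(op, left, right) / list(op, arg) / marker name).
ast_eval <- function(ast, env) {
  if (is.character(ast)) return(as.logical(env[[ast]]))
  switch(ast$op,
    YES = ast_eval(ast$arg, env),
    NOT = !ast_eval(ast$arg, env),
    OR = ast_eval(ast$left, env) || ast_eval(ast$right, env),
    AND = ast_eval(ast$left, env) && ast_eval(ast$right, env),
    ANDNOT = ast_eval(ast$left, env) && !ast_eval(ast$right, env)
  )
}

ast_render <- function(ast) {
  if (is.character(ast)) return(ast)
  switch(ast$op,
    YES = paste0("YES (", ast_render(ast$arg), ")"),
    NOT = paste0("NOT (", ast_render(ast$arg), ")"),
    OR = paste0("(", ast_render(ast$left), " OR ", ast_render(ast$right), ")"),
    AND = paste0("(", ast_render(ast$left), " AND ", ast_render(ast$right), ")"),
    ANDNOT = paste0("(", ast_render(ast$left), " AND-NOT ",
                    ast_render(ast$right), ")")
  )
}

ast_random <- function(depth, markers) {
  if (depth == 0 || runif(1) < 0.3) return(sample(markers, 1))
  op <- sample(c("YES", "NOT", "OR", "AND", "ANDNOT"), 1)
  if (op %in% c("YES", "NOT")) {
    list(op = op, arg = ast_random(depth - 1, markers))
  } else {
    list(op = op, left = ast_random(depth - 1, markers),
         right = ast_random(depth - 1, markers))
  }
}

gate_truth <- list(
  YES = function(x, y) x,
  NOT = function(x, y) !x,
  OR = function(x, y) x | y,
  AND = function(x, y) x & y,
  ANDNOT = function(x, y) x & !y
)

test_that("all five gates reproduce their truth tables (10 rows total)", {
  rows <- 0L
  for (kind in names(gate_truth)) {
    unary <- kind %in% c("YES", "NOT")
    circ <- logic_circuit(list(
      logic_gate(kind, if (unary) "A" else c("A", "B"), "out")
    ))
    tab <- truth_table(circ)
    expect_equal(nrow(tab), if (unary) 2L else 4L)
    rows <- rows + nrow(tab)
    for (i in seq_len(nrow(tab))) {
      want <- gate_truth[[kind]](tab$A[i] == 1,
                                 if (unary) NA else tab$B[i] == 1)
      expect_identical(tab$out_out[i], want)
    }
  }
  expect_equal(rows, 2L + 2L + 4L + 4L + 4L)
})

test_that("the three-input CTC classifier circuit matches its 8-row table", {
  circ <- parse_logic_expression("(KRT19 OR VIM) AND-NOT PTPRC")
  expect_equal(length(circ$inputs), 3)
  expect_equal(length(circ$gates), 2)
  tab <- truth_table(circ)
  expect_equal(nrow(tab), 8)
  out_col <- grep("^out_", names(tab), value = TRUE)
  on_rows <- tab[tab[[out_col]], c("KRT19", "VIM", "PTPRC")]
  want <- data.frame(KRT19 = c(0L, 1L, 1L), VIM = c(1L, 0L, 1L),
                     PTPRC = c(0L, 0L, 0L))
  expect_equal(on_rows[order(on_rows$KRT19, on_rows$VIM), ],
               want, ignore_attr = TRUE)
})

test_that("signal-level calls agree with Boolean evaluation at default params", {
  # single gates, exhaustively
  for (kind in names(gate_truth)) {
    unary <- kind %in% c("YES", "NOT")
    circ <- logic_circuit(list(
      logic_gate(kind, if (unary) "A" else c("A", "B"), "out")
    ))
    tab <- truth_table(circ, signal = TRUE)
    expect_identical(tab$call_out, tab$out_out)
  }
  # the paper-style two-level circuit, all 2^3 assignments
  circ <- parse_logic_expression("(KRT19 OR VIM) AND-NOT PTPRC")
  tab <- truth_table(circ, signal = TRUE)
  out_col <- grep("^out_", names(tab), value = TRUE)
  call_col <- grep("^call_", names(tab), value = TRUE)
  expect_identical(tab[[call_col]], tab[[out_col]])
  # random depth-2 circuits
  set.seed(19)
  for (i in 1:25) {
    ast <- ast_random(2, c("A", "B", "C"))
    circ <- parse_logic_expression(ast_render(ast))
    tab <- truth_table(circ, signal = TRUE)
    expect_identical(tab[[grep("^call_", names(tab), value = TRUE)]],
                     tab[[grep("^out_", names(tab), value = TRUE)]])
  }
})

test_that("AND-gate threshold strand sequesters a lone input", {
  p <- signal_params(on_level = 1, leak = 0, and_threshold = 1.2,
                     detect_cutoff = 0.5)
  circ <- logic_circuit(list(logic_gate("AND", c("A", "B"), "out")))
  s <- eval_signal(circ, c(A = 1, B = 0), p)
  expect_equal(unname(s$output_levels), 0)  # max(0, on - threshold), thr > on
  expect_false(unname(s$calls))
  both <- eval_signal(circ, c(A = 1, B = 1), p)
  expect_true(unname(both$calls))
})

test_that("parameter sets where leak would read as ON are rejected", {
  # leak above the detect cutoff guarantees false-ON transducer readouts;
  # the constructor exposes this failure mode instead of permitting it
  expect_error(signal_params(leak = 0.6, detect_cutoff = 0.5), "detect_cutoff")
  expect_error(signal_params(and_threshold = 0.01), "and_threshold")
})

test_that("truth tables have 2^k deterministic binary-counter rows", {
  yes <- parse_logic_expression("YES X")
  tab <- truth_table(yes)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$X, c(0L, 1L))
  expect_equal(tab[[grep("^out_", names(tab))]], c(FALSE, TRUE))
  or_tab <- truth_table(parse_logic_expression("A OR B"))
  expect_equal(sum(!or_tab[[grep("^out_", names(or_tab))]]), 1)  # one OFF row
  expect_equal(or_tab$A, c(0L, 0L, 1L, 1L))
  expect_equal(or_tab$B, c(0L, 1L, 0L, 1L))
})

test_that("parsed expressions agree with a reference recursive evaluator", {
  set.seed(23)
  markers <- c("KRT19", "VIM", "PTPRC")
  for (i in 1:50) {
    ast <- ast_random(4, markers)
    circ <- parse_logic_expression(ast_render(ast))
    used <- circ$inputs
    k <- length(used)
    for (code in 0:(2^k - 1)) {
      bits <- as.integer(intToBits(code))[seq_len(k)]
      env <- as.list(stats::setNames(bits, used))
      got <- unname(eval_boolean(circ, unlist(env)))
      expect_identical(got, ast_eval(ast, env))
    }
  }
})

test_that("the gate set is functionally complete: XOR and De Morgan hold", {
  xor_circ <- parse_logic_expression("(A AND-NOT B) OR (B AND-NOT A)")
  tab <- truth_table(xor_circ, signal = TRUE)
  expect_equal(tab[[grep("^out_", names(tab), value = TRUE)]],
               xor(tab$A == 1, tab$B == 1))
  expect_identical(tab[[grep("^call_", names(tab), value = TRUE)]],
                   tab[[grep("^out_", names(tab), value = TRUE)]])
  # NOT(x OR y) == NOT(x) AND-NOT y on all assignments
  lhs <- truth_table(parse_logic_expression("NOT (A OR B)"))
  rhs <- truth_table(parse_logic_expression("(NOT A) AND-NOT B"))
  expect_equal(lhs[[grep("^out_", names(lhs))]], rhs[[grep("^out_", names(rhs))]])
})

test_that("malformed circuits and expressions fail loudly", {
  expect_error(logic_gate("XOR", c("A", "B")), "unknown gate kind")
  expect_error(logic_gate("NOT", c("A", "B")), "1 input")
  expect_error(logic_gate("AND", "A"), "2 input")
  expect_error(logic_circuit(list(
    logic_gate("YES", "b", "a"), logic_gate("YES", "a", "b")
  )), "cycle")
  expect_error(parse_logic_expression("A OR"), "position")
  expect_error(parse_logic_expression("(A OR B"), "position")
  expect_error(parse_logic_expression("A B"), "position")
  circ <- parse_logic_expression("A AND B")
  expect_error(eval_boolean(circ, c(A = 1)), "missing marker")
})
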
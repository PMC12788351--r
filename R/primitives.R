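# Vectorized primitive semantics. Every function receives full-length numeric
# vectors (one entry per patch) and returns the same length; intermediate
# values are unbounded, only the tree root is clipped.

pdiv_eps <- 1e-12

#' Genetic-programming primitive registry
#'
#' The complete function and terminal set of the patch-to-pixel GP: binary
#' arithmetic (`Add`, `Subtract`, `Multiply`, `ProtectedDivision`), unary
#' arithmetic (`Minus`, `Square`, `Tri` = cube, signed `SquareRoot`,
#' `Complement` = 1 - x), k-ary extrema (`Min3/6/9`, `Max3/6/9`, arity equal
#' to the suffix), and the conditionals `If_Then_Else(x, y, z)` (y if
#' x > 0.5 else z), `If_Larger(x, y, z, t)` (z if x > y else t) and
#' `If_In_Range(x, y, z, t, w)` (t if y <= x < z else w). Protected division
#' returns 1 whenever |denominator| < 1e-12. Terminals are the patch pixels
#' `Pixel1 ... PixelN^2` (row-major within the patch), the fixed constants
#' {0, 0.25, 0.5, 0.75, 1} and an ephemeral uniform-[0,1] constant.
#'
#' @param patch_width Side length N of the square pixel neighborhood
#'   (default 5, giving terminals Pixel1..Pixel25).
#' @return A list with `functions` (name -> list(arity, fun)), `constants`,
#'   `n_pixels`, `patch_width`.
#' @export
gp_primitives <- function(patch_width = 5) {
  if (patch_width %% 2 != 1 || patch_width < 1) {
    stop("`patch_width` must be a positive odd integer", call. = FALSE)
  }
  kary <- function(f, k) function(args) do.call(f, args[seq_len(k)])
  pick_if <- function(cond, yes, no) {
    cond[is.na(cond)] <- FALSE # NaN comparisons take the "else" branch
    out <- no
    out[cond] <- yes[cond]
    out
  }
  cond_ite <- function(args) pick_if(args[[1]] > 0.5, args[[2]], args[[3]])
  cond_larger <- function(args) pick_if(args[[1]] > args[[2]], args[[3]], args[[4]])
  cond_range <- function(args) {
    pick_if(args[[2]] <= args[[1]] & args[[1]] < args[[3]], args[[4]], args[[5]])
  }
  fns <- list(
    Add = list(arity = 2L, fun = function(a) a[[1]] + a[[2]]),
    Subtract = list(arity = 2L, fun = function(a) a[[1]] - a[[2]]),
    Multiply = list(arity = 2L, fun = function(a) a[[1]] * a[[2]]),
    ProtectedDivision = list(arity = 2L, fun = function(a) {
      out <- a[[1]] / a[[2]]
      out[abs(a[[2]]) < pdiv_eps] <- 1
      out
    }),
    Minus = list(arity = 1L, fun = function(a) -a[[1]]),
    Square = list(arity = 1L, fun = function(a) a[[1]]^2),
    Tri = list(arity = 1L, fun = function(a) a[[1]]^3),
    SquareRoot = list(arity = 1L, fun = function(a) sign(a[[1]]) * sqrt(abs(a[[1]]))),
    Complement = list(arity = 1L, fun = function(a) 1 - a[[1]]),
    Min3 = list(arity = 3L, fun = kary(pmin, 3)),
    Min6 = list(arity = 6L, fun = kary(pmin, 6)),
    Min9 = list(arity = 9L, fun = kary(pmin, 9)),
    Max3 = list(arity = 3L, fun = kary(pmax, 3)),
    Max6 = list(arity = 6L, fun = kary(pmax, 6)),
    Max9 = list(arity = 9L, fun = kary(pmax, 9)),
    If_Then_Else = list(arity = 3L, fun = cond_ite),
    If_Larger = list(arity = 4L, fun = cond_larger),
    If_In_Range = list(arity = 5L, fun = cond_range)
  )
  list(functions = fns,
       constants = c(0, 0.25, 0.5, 0.75, 1),
       n_pixels = patch_width^2L,
       patch_width = patch_width)
}

# Aliases accepted by the parser (names seen in rendered evolved trees).
PRIMITIVE_ALIASES <- c(
  Compl = "Complement", sqr = "Square", pDiv = "ProtectedDivision",
  "if.then.else" = "If_Then_Else", "if.larger" = "If_Larger",
  "if.in.range" = "If_In_Range", add = "Add", sub = "Subtract",
  mul = "Multiply", neg = "Minus", cube = "Tri", sqroot = "SquareRoot",
  min3 = "Min3", min6 = "Min6", min9 = "Min9",
  max3 = "Max3", max6 = "Max6", max9 = "Max9"
)

# --- tree nodes ---------------------------------------------------------
# A tree is a nested list: list(type = "fun", name, fun, args = list(...)),
# list(type = "pix", k) or list(type = "const", value).

node_fun <- function(name, args, prims) {
  spec <- prims$functions[[name]]
  if (is.null(spec)) stop(sprintf("unknown function '%s'", name), call. = FALSE)
  if (length(args) != spec$arity) {
    stop(sprintf("'%s' expects %d arguments, got %d",
                 name, spec$arity, length(args)), call. = FALSE)
  }
  list(type = "fun", name = name, fun = spec$fun, args = args)
}

node_pix <- function(k) list(type = "pix", k = as.integer(k))

node_const <- function(value) list(type = "const", value = as.numeric(value))

# Opcodes of the compiled postfix evaluator (src/eval_tree.cpp); the function
# order is fixed and shared between both interpreters.
OPCODES <- c(
  Add = 2L, Subtract = 3L, Multiply = 4L, ProtectedDivision = 5L,
  Minus = 6L, Square = 7L, Tri = 8L, SquareRoot = 9L, Complement = 10L,
  Min3 = 11L, Min6 = 12L, Min9 = 13L, Max3 = 14L, Max6 = 15L, Max9 = 16L,
  If_Then_Else = 17L, If_Larger = 18L, If_In_Range = 19L
)

# Flatten a tree into postfix opcode/aux arrays for the compiled evaluator.
tree_postfix <- function(tree) {
  ops <- integer(0)
  aux <- numeric(0)
  stack <- list(tree)
  # iterative post-order: emit children before parents
  out_ops <- integer(tree_size(tree))
  out_aux <- numeric(length(out_ops))
  pos <- length(out_ops)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node$type == "fun") {
      out_ops[pos] <- OPCODES[[node$name]]
      out_aux[pos] <- 0
      pos <- pos - 1L
      # push args left-to-right so they pop right-to-left (reverse postfix)
      for (a in node$args) stack[[length(stack) + 1L]] <- a
    } else if (node$type == "pix") {
      out_ops[pos] <- 1L
      out_aux[pos] <- node$k
      pos <- pos - 1L
    } else {
      out_ops[pos] <- 0L
      out_aux[pos] <- node$value
      pos <- pos - 1L
    }
  }
  list(ops = out_ops, aux = out_aux)
}

eval_node <- function(node, P) {
  switch(node$type,
    pix = P[, node$k],
    const = rep.int(node$value, nrow(P)),
    fun = node$fun(lapply(node$args, eval_node, P = P))
  )
}

# Evaluate a tree on a patch matrix (rows = patches, cols = Pixel1..PixelN^2),
# clipping only the root output to [0, 1] (non-finite values map to 0 for NaN
# and to the clip bounds for +/-Inf). Dispatches to the compiled postfix
# evaluator; eval_tree_matrix_r is the pure-R path with identical semantics.
eval_tree_matrix <- function(tree, P) {
  pf <- tree_postfix(tree)
  .eval_postfix(pf$ops, pf$aux, P)
}

eval_tree_matrix_r <- function(tree, P) {
  v <- eval_node(tree, P)
  if (length(v) == 1L) v <- rep.int(v, nrow(P))
  v[is.na(v)] <- 0
  pmin(pmax(v, 0), 1)
}

#' Evaluate a GP tree on one pixel neighborhood
#'
#' Recursively evaluates the expression tree on a single N x N patch of pixel
#' values. Intermediate node values are unbounded; only the root return is
#' clipped to [0, 1]. The evaluation is total: any numeric input yields a
#' finite result (NaN maps to 0, infinities clip to the range bounds).
#'
#' @param tree A GP tree (from [random_tree()], [parse_tree()] or evolution).
#' @param patch An N x N matrix (read row-major into Pixel1..PixelN^2) or a
#'   length-N^2 vector already in row-major pixel order.
#' @param patch_width Side length N (default 5).
#' @return A single value in [0, 1].
#' @export
eval_tree <- function(tree, patch, patch_width = 5) {
  n <- patch_width^2
  if (is.matrix(patch)) {
    if (!all(dim(patch) == patch_width)) {
      stop(sprintf("`patch` must be %d x %d", patch_width, patch_width),
           call. = FALSE)
    }
    patch <- as.vector(t(patch)) # row-major pixel numbering
  }
  if (length(patch) != n) {
    stop(sprintf("`patch` must contain %d values", n), call. = FALSE)
  }
  eval_tree_matrix(tree, matrix(as.numeric(patch), nrow = 1))
}

# --- structural helpers -------------------------------------------------

#' Tree depth and size
#'
#' Depth counts edges on the longest root-to-leaf path (a lone terminal has
#' depth 0); size counts nodes.
#'
#' @param tree A GP tree.
#' @return An integer.
#' @export
tree_depth <- function(tree) {
  if (tree$type != "fun") return(0L)
  1L + max(vapply(tree$args, tree_depth, integer(1)))
}

#' @rdname tree_depth
#' @export
tree_size <- function(tree) {
  if (tree$type != "fun") return(1L)
  1L + sum(vapply(tree$args, tree_size, integer(1)))
}

# Pre-order subtree access/replacement (index 1 = root).
get_subtree <- function(tree, index) {
  env <- new.env()
  env$i <- 0L
  env$hit <- NULL
  rec <- function(node) {
    env$i <- env$i + 1L
    if (env$i == index) {
      env$hit <- node
      return(invisible())
    }
    if (node$type == "fun" && is.null(env$hit)) {
      for (a in node$args) {
        rec(a)
        if (!is.null(env$hit)) break
      }
    }
    invisible()
  }
  rec(tree)
  env$hit
}

replace_subtree <- function(tree, index, replacement) {
  counter <- new.env()
  counter$i <- 0L
  rec <- function(node) {
    counter$i <- counter$i + 1L
    if (counter$i == index) return(replacement)
    if (node$type == "fun") {
      node$args <- lapply(node$args, rec)
    }
    node
  }
  rec(tree)
}

# --- random generation --------------------------------------------------

random_terminal <- function(prims) {
  # pixels, fixed constants and the ephemeral constant drawn uniformly
  n_opts <- prims$n_pixels + length(prims$constants) + 1L
  pick <- sample.int(n_opts, 1L)
  if (pick <= prims$n_pixels) {
    node_pix(pick)
  } else if (pick <= prims$n_pixels + length(prims$constants)) {
    node_const(prims$constants[pick - prims$n_pixels])
  } else {
    node_const(stats::runif(1))
  }
}

#' Generate a random GP tree
#'
#' `"full"` places functions at every node above `max_depth` and terminals at
#' `max_depth`; `"grow"` may stop early but never before `min_depth` on any
#' path (terminals are only eligible once a branch has reached `min_depth`).
#'
#' @param prims A [gp_primitives()] registry.
#' @param min_depth,max_depth Depth constraints (edges; see [tree_depth()]).
#' @param method `"grow"` or `"full"`.
#' @return A GP tree.
#' @export
random_tree <- function(prims, min_depth = 3, max_depth = 5,
                        method = c("grow", "full")) {
  method <- match.arg(method)
  fn_names <- names(prims$functions)
  n_term <- prims$n_pixels + length(prims$constants) + 1L
  term_ratio <- n_term / (n_term + length(fn_names))
  rec <- function(depth) {
    pick_terminal <- if (depth >= max_depth) {
      TRUE
    } else if (method == "full") {
      FALSE
    } else {
      depth >= min_depth && stats::runif(1) < term_ratio
    }
    if (pick_terminal) return(random_terminal(prims))
    nm <- fn_names[sample.int(length(fn_names), 1L)]
    arity <- prims$functions[[nm]]$arity
    node_fun(nm, lapply(seq_len(arity), function(i) rec(depth + 1L)), prims)
  }
  rec(0L)
}

# --- serialization ------------------------------------------------------

#' Serialize a GP tree to an s-expression
#'
#' Losslessly renders a tree as a LISP-style s-expression, e.g.
#' `"(Add Pixel13 (Complement 0.25))"`. [parse_tree()] inverts it.
#'
#' @param tree A GP tree.
#' @return A single string.
#' @export
serialize_tree <- function(tree) {
  switch(tree$type,
    pix = paste0("Pixel", tree$k),
    const = sprintf("%.17g", tree$value),
    fun = paste0("(", tree$name, " ",
                 paste(vapply(tree$args, serialize_tree, character(1)),
                       collapse = " "), ")")
  )
}

#' Parse an s-expression into a GP tree
#'
#' Accepts the canonical operator names of [gp_primitives()] plus the short
#' aliases used in rendered trees (`Compl`, `sqr`, `pDiv`, `min3`, `max9`,
#' `if.then.else`, ...). Unknown operators and arity mismatches are rejected
#' with the offending token and its position.
#'
#' @param text An s-expression string.
#' @param patch_width Side length N of the pixel neighborhood (default 5).
#' @return A GP tree.
#' @export
parse_tree <- function(text, patch_width = 5) {
  text <- paste(text, collapse = " ") # accept readLines() output
  prims <- gp_primitives(patch_width)
  toks <- strsplit(gsub("\\)", " ) ", gsub("\\(", " ( ", text)), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty expression", call. = FALSE)
  pos <- new.env()
  pos$i <- 0L
  next_tok <- function() {
    pos$i <- pos$i + 1L
    if (pos$i > length(toks)) {
      stop(sprintf("unexpected end of input at token %d", pos$i), call. = FALSE)
    }
    toks[pos$i]
  }
  atom <- function(tok) {
    if (grepl("^Pixel[0-9]+$", tok)) {
      k <- as.integer(sub("Pixel", "", tok))
      if (k < 1 || k > prims$n_pixels) {
        stop(sprintf("pixel index out of range in '%s' at token %d", tok, pos$i),
             call. = FALSE)
      }
      return(node_pix(k))
    }
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) {
      stop(sprintf("unknown terminal '%s' at token %d", tok, pos$i),
           call. = FALSE)
    }
    node_const(v)
  }
  rec <- function() {
    tok <- next_tok()
    if (tok == ")") stop(sprintf("unexpected ')' at token %d", pos$i), call. = FALSE)
    if (tok != "(") return(atom(tok))
    op <- next_tok()
    canon <- if (op %in% names(prims$functions)) {
      op
    } else if (op %in% names(PRIMITIVE_ALIASES)) {
      PRIMITIVE_ALIASES[[op]]
    } else {
      stop(sprintf("unknown operator '%s' at token %d", op, pos$i), call. = FALSE)
    }
    args <- list()
    repeat {
      if (pos$i + 1L > length(toks)) {
        stop(sprintf("missing ')' at token %d", pos$i), call. = FALSE)
      }
      if (toks[pos$i + 1L] == ")") {
        pos$i <- pos$i + 1L
        break
      }
      args[[length(args) + 1L]] <- rec()
    }
    node_fun(canon, args, prims)
  }
  out <- rec()
  if (pos$i != length(toks)) {
    stop(sprintf("trailing input at token %d ('%s')", pos$i + 1L,
                 toks[pos$i + 1L]), call. = FALSE)
  }
  out
}
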
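#' @useDynLib apunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse-mode automatic differentiation on a dynamically recorded tape.
#
# A tensor is an environment holding a numeric array (`value`), its
# accumulated gradient (`grad`), the tensors it was computed from
# (`parents`) and a closure (`backfn`) mapping the gradient at this node to
# the gradients of its parents. Operations in ops.R build the graph; a
# single call to ag_backward() on a scalar loss propagates gradients to
# every parameter reachable from it.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

new_tensor <- function(value, parents = list(), backfn = NULL) {
  t <- new.env(parent = emptyenv())
  .ag$counter <- .ag$counter + 1L
  t$id <- .ag$counter
  t$value <- value
  t$grad <- NULL
  t$parents <- parents
  t$backfn <- backfn
  t$is_param <- FALSE
  t$requires_grad <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  class(t) <- "ag_tensor"
  t
}

ag_param <- function(value) {
  t <- new_tensor(value)
  t$is_param <- TRUE
  t$requires_grad <- TRUE
  t
}

ag_const <- function(value) new_tensor(value)

is_tensor <- function(x) inherits(x, "ag_tensor")

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (is.null(d)) paste0("len ", length(x$value))
      else paste(d, collapse = "x"),
      if (x$is_param) "param" else "", ">\n")
  invisible(x)
}

# Depth-first post-order over the subgraph that requires gradients.
ag_topo <- function(root) {
  topo <- vector("list", 256L)
  nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    stack[[ns]] <- NULL
    ns <- ns - 1L
    node <- fr$node
    key <- as.character(node$id)
    if (fr$expanded) {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
      next
    }
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    ns <- ns + 1L
    stack[[ns]] <- list(node = node, expanded = TRUE)
    for (p in node$parents) {
      if (p$requires_grad && is.null(seen[[as.character(p$id)]])) {
        ns <- ns + 1L
        stack[[ns]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  topo[seq_len(nt)]
}

# Backpropagate from a scalar root (seed gradient 1).
ag_backward <- function(root) {
  stopifnot(is_tensor(root), length(root$value) == 1L)
  if (!root$requires_grad) return(invisible(NULL))
  topo <- ag_topo(root)
  root$grad <- 1
  for (i in rev(seq_along(topo))) {
    node <- topo[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (!p$requires_grad || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
    if (!node$is_param) node$grad <- NULL  # free intermediate gradients
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
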
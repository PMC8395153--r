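#' Construct a ternary regulatory network
#'
#' A network holds named nodes (with free-text role tags), signed directed
#' edges, and an optional condition ("gate") per edge. A gated edge contributes
#' to its target's image only while the gate node sits at the required value;
#' the packaged neuroimmune model uses this for interactions across the
#' blood-brain barrier, which are only allowed while the `EndothelialCells`
#' node is -1. Nodes tagged with role `"external"` are external drives: they
#' have no regulatory inputs and are clamped to a fixed value during
#' simulation (0 unless overridden via `clamp`).
#'
#' @param nodes character vector of unique node names.
#' @param edges data.frame with columns `source`, `target`,
#'   `mode` (`"activate"` or `"inhibit"`) and optionally `gate_node`,
#'   `gate_value` (NA for unconditional edges).
#' @param roles character vector of role tags, recycled to `length(nodes)`.
#' @param clamp named integer vector of clamp values for external nodes
#'   (defaults to 0 for every external node).
#' @return An object of class `ternet_network`.
#' @export
ternet_network <- function(nodes, edges, roles = "node", clamp = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node ids must be unique", call. = FALSE)
  roles <- rep_len(as.character(roles), length(nodes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "mode")
  if (!all(need %in% names(edges)))
    stop("edges need columns source, target, mode", call. = FALSE)
  if (is.null(edges$gate_node))
    edges$gate_node <- rep(NA_character_, nrow(edges))
  if (is.null(edges$gate_value))
    edges$gate_value <- rep(NA_integer_, nrow(edges))
  edges <- edges[, c("source", "target", "mode", "gate_node", "gate_value")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$gate_node <- as.character(edges$gate_node)
  edges$gate_value <- as.integer(edges$gate_value)

  bad <- setdiff(c(edges$source, edges$target,
                   edges$gate_node[!is.na(edges$gate_node)]), nodes)
  if (length(bad))
    stop("unknown node(s) in edge list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(edges$mode %in% c("activate", "inhibit")))
    stop("edge mode must be 'activate' or 'inhibit'", call. = FALSE)
  gated <- !is.na(edges$gate_node)
  if (any(gated & is.na(edges$gate_value)))
    stop("conditional edges need a gate value", call. = FALSE)
  if (any(!gated & !is.na(edges$gate_value)))
    stop("gate value given without gate node", call. = FALSE)
  if (any(gated & edges$gate_node == edges$target))
    stop("an edge's gate may not be its own target", call. = FALSE)
  if (any(gated & !edges$gate_value %in% c(-1L, 0L, 1L)))
    stop("gate value must be ternary", call. = FALSE)

  external <- roles == "external"
  cl <- rep(0L, length(nodes)); names(cl) <- nodes
  if (!is.null(clamp)) {
    if (is.null(names(clamp)) || !all(names(clamp) %in% nodes))
      stop("clamp must be named by node", call. = FALSE)
    cl[names(clamp)] <- check_ternary(clamp, "clamp")
  }
  # external drives must not have regulatory inputs
  if (any(edges$target %in% nodes[external]))
    stop("external nodes cannot be edge targets", call. = FALSE)

  structure(list(nodes = nodes, roles = roles, external = external,
                 clamp = cl, edges = edges),
            class = "ternet_network")
}

#' @export
print.ternet_network <- function(x, ...) {
  ng <- sum(!is.na(x$edges$gate_node))
  cat("ternet_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(%d conditional), %d external drive(s)\n",
              ng, sum(x$external)))
  invisible(x)
}

#' @export
`==.ternet_network` <- function(e1, e2) {
  identical(e1$nodes, e2$nodes) && identical(e1$roles, e2$roles) &&
    identical(e1$clamp, e2$clamp) &&
    identical(canon_edges(e1$edges), canon_edges(e2$edges))
}

canon_edges <- function(e) {
  o <- order(e$target, e$source, e$mode, e$gate_node, e$gate_value,
             na.last = TRUE)
  e <- e[o, , drop = FALSE]
  rownames(e) <- NULL
  e
}

# ---- integer encoding passed to the C++ engine -------------------------------

net_encode <- function(net) {
  idx <- function(v) match(v, net$nodes) - 1L
  e <- net$edges
  list(
    n = length(net$nodes),
    src = idx(e$source),
    tgt = idx(e$target),
    mode = ifelse(e$mode == "activate", 1L, -1L),
    gate = ifelse(is.na(e$gate_node), -1L, idx(e$gate_node)),
    gate_val = ifelse(is.na(e$gate_value), 0L, e$gate_value),
    external = which(net$external) - 1L,
    clamp = as.integer(net$clamp)
  )
}

as_state <- function(state, net) {
  if (is.null(names(state)))
    stop("state vector must be named by node", call. = FALSE)
  if (length(state) != length(net$nodes) || !setequal(names(state), net$nodes))
    stop("state must cover exactly the network's nodes", call. = FALSE)
  check_ternary(state[net$nodes], "state")
}

#' Image vector of a state
#'
#' Computes the state toward which the system prefers to evolve in the next
#' time increment. Per node the active activators are aggregated with the
#' ternary OR, the active inhibitors likewise, and the two aggregates are
#' combined with the ternary PASS operator (both present), passed through
#' unchanged (activators only) or inverted with the ternary NOT (inhibitors
#' only). Conditional edges are evaluated against the *current* state of
#' their gate node. Nodes without (active) inputs, and external drives, keep
#' their current value.
#'
#' @param state named ternary vector covering all network nodes.
#' @param net a [ternet_network].
#' @return Named ternary image vector in the network's node order.
#' @export
image_vector <- function(state, net) {
  x <- as_state(state, net)
  out <- cpp_image(x, net_encode(net))
  names(out) <- net$nodes
  out
}

#' Test whether a state is a fixed point of the network logic
#' @inheritParams image_vector
#' @return TRUE if the image vector equals the state.
#' @export
is_fixed_point <- function(state, net) {
  x <- as_state(state, net)
  all(cpp_image(x, net_encode(net)) == x)
}

# ---- file format -------------------------------------------------------------

#' Read / write the TSV network format
#'
#' One record per line, tab separated, `#` starts a comment. Node declarations
#' come first: `node <tab> NAME <tab> ROLE` (role `external` marks an external
#' drive, optionally `node NAME external=VALUE` clamp syntax via a fourth
#' field `clamp=V`). Edges follow: `edge <tab> SOURCE <tab> TARGET <tab>
#' activate|inhibit [<tab> GATE=VALUE]`.
#'
#' @param path file path.
#' @param net a [ternet_network].
#' @return `read_network` returns a [ternet_network]; `write_network`
#'   invisibly returns `path`. Writing then reading reproduces the model.
#' @export
read_network <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", raw)
  keep <- which(trimws(lines) != "")
  nodes <- character(); roles <- character(); clamp <- integer()
  edges <- list()
  for (ln in keep) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    f <- trimws(f); f <- f[f != ""]
    kind <- f[1]
    if (kind == "node") {
      if (length(f) < 3)
        stop(sprintf("line %d: node record needs NAME and ROLE", ln),
             call. = FALSE)
      nodes <- c(nodes, f[2]); roles <- c(roles, f[3])
      if (length(f) >= 4) {
        cv <- strsplit(f[4], "=", fixed = TRUE)[[1]]
        if (length(cv) != 2 || cv[1] != "clamp")
          stop(sprintf("line %d: malformed clamp field '%s'", ln, f[4]),
               call. = FALSE)
        clamp[f[2]] <- as.integer(cv[2])
      }
    } else if (kind == "edge") {
      if (length(f) < 4 || !f[4] %in% c("activate", "inhibit"))
        stop(sprintf(
          "line %d: edge record needs SOURCE TARGET activate|inhibit", ln),
          call. = FALSE)
      gn <- NA_character_; gv <- NA_integer_
      if (length(f) >= 5) {
        g <- strsplit(f[5], "=", fixed = TRUE)[[1]]
        if (length(g) != 2 || is.na(suppressWarnings(as.integer(g[2]))))
          stop(sprintf("line %d: malformed condition '%s'", ln, f[5]),
               call. = FALSE)
        gn <- g[1]; gv <- as.integer(g[2])
      }
      if (!all(c(f[2], f[3]) %in% nodes))
        stop(sprintf("line %d: edge refers to undeclared node", ln),
             call. = FALSE)
      edges[[length(edges) + 1L]] <-
        data.frame(source = f[2], target = f[3], mode = f[4],
                   gate_node = gn, gate_value = gv,
                   stringsAsFactors = FALSE)
    } else {
      stop(sprintf("line %d: unknown record type '%s'", ln, kind),
           call. = FALSE)
    }
  }
  ternet_network(nodes, do.call(rbind, edges), roles,
                 clamp = if (length(clamp)) clamp else NULL)
}

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# ternet network file", con)
  for (i in seq_along(net$nodes)) {
    rec <- c("node", net$nodes[i], net$roles[i])
    if (net$external[i] && net$clamp[i] != 0L)
      rec <- c(rec, paste0("clamp=", net$clamp[i]))
    writeLines(paste(rec, collapse = "\t"), con)
  }
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    rec <- c("edge", e$source[i], e$target[i], e$mode[i])
    if (!is.na(e$gate_node[i]))
      rec <- c(rec, paste0(e$gate_node[i], "=", e$gate_value[i]))
    writeLines(paste(rec, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a stable-state catalogue
#'
#' TSV with one row per node and one column per state (`SS0`, `SS1`, ...),
#' entries in -1/0/1.
#'
#' @param path file path.
#' @param states matrix (nodes x states) or list of named state vectors.
#' @return `read_states` returns an integer matrix, rows named by node,
#'   columns by state.
#' @export
read_states <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  if (!all(m %in% c(-1L, 0L, 1L))) stop("catalogue entries must be ternary")
  m
}

#' @rdname read_states
#' @export
write_states <- function(states, path) {
  m <- if (is.matrix(states)) states else do.call(cbind, states)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
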
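#' Network architecture of the mismatch network
#'
#' Six-node architecture with binary forward/backward/lateral adjacency
#' matrices (rows = target, columns = source), exogenous-input indicators
#' and the mask of connections whose gain is modulated by the deviant
#' condition. Forward edges deliver superficial-pyramidal output to the
#' target's spiny stellate and deep pyramidal populations; backward edges
#' deliver deep-pyramidal output to the target's superficial pyramidal and
#' inhibitory populations. Exogenous and latent inputs arrive in the
#' granular layer (SS) of their target nodes.
#'
#' @param nodes Ordered node labels.
#' @param A_fwd,A_bwd,A_lat Binary adjacency matrices (no self-edges).
#' @param C Exogenous (sensory) input indicator per node.
#' @param latent Latent (top-down) input indicator per node.
#' @param B_fwd,B_bwd,B_lat Binary masks of condition-modulated edges.
#' @param B_self Logical per node: is the SP self-gain condition-modulated?
#' @param model_id Integer id (1-21) within the model space, or NA.
#' @param mod_classes Character subset of `c("F","B","self")` recording which
#'   connection classes carry the deviant modulation.
#' @param reconstructed Flag: TRUE where the exact edge/modulation layout is
#'   a documented convention rather than a pinned-down fact.
#' @return Object of class `network_architecture`.
#' @export
network_architecture <- function(nodes = cmc_nodes(),
                                 A_fwd, A_bwd, A_lat = NULL,
                                 C, latent = NULL,
                                 B_fwd = NULL, B_bwd = NULL, B_lat = NULL,
                                 B_self = NULL,
                                 model_id = NA_integer_,
                                 mod_classes = character(),
                                 reconstructed = FALSE) {
  n <- length(nodes)
  zero <- matrix(0, n, n, dimnames = list(nodes, nodes))
  fix <- function(m) {
    if (is.null(m)) return(zero)
    dimnames(m) <- list(nodes, nodes)
    m
  }
  A_fwd <- fix(A_fwd); A_bwd <- fix(A_bwd); A_lat <- fix(A_lat)
  B_fwd <- fix(B_fwd); B_bwd <- fix(B_bwd); B_lat <- fix(B_lat)
  for (m in list(A_fwd, A_bwd, A_lat))
    if (any(diag(m) != 0)) stop("adjacency matrices must have no self-edges")
  if (is.null(latent)) latent <- rep(0, n)
  if (is.null(B_self)) B_self <- rep(FALSE, n)
  structure(list(nodes = nodes,
                 A_fwd = A_fwd, A_bwd = A_bwd, A_lat = A_lat,
                 C = setNames(rep_len(as.numeric(C), n), nodes),
                 latent = setNames(rep_len(as.numeric(latent), n), nodes),
                 B_fwd = B_fwd, B_bwd = B_bwd, B_lat = B_lat,
                 B_self = setNames(rep_len(B_self, n), nodes),
                 model_id = as.integer(model_id),
                 mod_classes = mod_classes,
                 reconstructed = reconstructed),
            class = "network_architecture")
}

# the six deviant-modulation combinations cycled over within each family
.mod_combos <- list(c("F"), c("B"), c("F", "B"),
                    c("F", "self"), c("B", "self"), c("F", "B", "self"))

# assemble one architecture from its axes
.build_arch <- function(id, lifg, interhemi, latent_rifg, combo,
                        nodes = cmc_nodes(), reconstructed = TRUE) {
  n <- length(nodes)
  A_fwd <- A_bwd <- A_lat <- matrix(0, n, n, dimnames = list(nodes, nodes))
  edge <- function(m, from, to) { m[to, from] <- 1; m }

  # obligatory auditory hierarchy plus right-hemisphere frontal level
  A_fwd <- edge(A_fwd, "lA1", "lSTG"); A_fwd <- edge(A_fwd, "rA1", "rSTG")
  A_fwd <- edge(A_fwd, "rSTG", "rIFG")
  A_bwd <- edge(A_bwd, "lSTG", "lA1"); A_bwd <- edge(A_bwd, "rSTG", "rA1")
  A_bwd <- edge(A_bwd, "rIFG", "rSTG")
  if (lifg) {
    A_fwd <- edge(A_fwd, "lSTG", "lIFG")
    A_bwd <- edge(A_bwd, "lIFG", "lSTG")
  }
  if (interhemi) {
    A_lat <- edge(A_lat, "lA1", "rA1");  A_lat <- edge(A_lat, "rA1", "lA1")
    A_lat <- edge(A_lat, "lSTG", "rSTG"); A_lat <- edge(A_lat, "rSTG", "lSTG")
  }

  C <- as.numeric(nodes %in% c("lA1", "rA1"))
  latent <- as.numeric(latent_rifg & nodes == "rIFG")

  connected <- rowSums(A_fwd + A_bwd + A_lat) +
    colSums(A_fwd + A_bwd + A_lat) > 0
  B_self <- rep(FALSE, n)
  if ("self" %in% combo) B_self <- connected

  network_architecture(
    nodes = nodes, A_fwd = A_fwd, A_bwd = A_bwd, A_lat = A_lat,
    C = C, latent = latent,
    B_fwd = if ("F" %in% combo) A_fwd else NULL,
    B_bwd = if ("B" %in% combo) A_bwd else NULL,
    B_lat = if ("self" %in% combo) A_lat else NULL,
    B_self = B_self,
    model_id = id, mod_classes = combo, reconstructed = reconstructed)
}

#' Build the 21-model architecture space
#'
#' Enumerates the 21 candidate architectures of the mismatch network as the
#' product of four axes: presence of left IFG connectivity, presence of
#' interhemispheric lateral connections, presence of a top-down latent input
#' to right IFG, and which connection classes (forward, backward,
#' lateral-or-self) carry the deviant modulation. Family memberships are
#' fixed: models 7, 8, 10-13, 15, 16 and 18-21 include left IFG; models 9
#' and 17 carry interhemispheric connections; model 14 alone has the right
#' IFG latent input and is otherwise identical to model 6. Every model
#' receives exogenous input to bilateral A1.
#'
#' @param nodes Node labels (6 sources).
#' @return Object of class `model_space`: list of 21
#'   [network_architecture()]s plus the 3-level family tree.
#' @export
build_model_space <- function(nodes = cmc_nodes()) {
  if (length(nodes) != 6) stop("the model space is defined over 6 named nodes")
  models <- vector("list", 21)
  put <- function(id, lifg, ih, lat_in, combo, rec = TRUE)
    models[[id]] <<- .build_arch(id, lifg, ih, lat_in, .mod_combos[[combo]],
                                 nodes, reconstructed = rec)
  # without-lIFG family
  for (i in 1:6) put(i, FALSE, FALSE, FALSE, i)
  put(9, FALSE, TRUE, FALSE, 3)
  put(17, FALSE, TRUE, FALSE, 6)
  put(14, FALSE, FALSE, TRUE, 6, rec = FALSE) # = model 6 + rIFG latent input
  # with-lIFG family: six modulation combos without, then with, latent input
  ids_no_latent <- c(7, 8, 10, 11, 12, 13)
  ids_latent <- c(15, 16, 18, 19, 20, 21)
  for (k in 1:6) put(ids_no_latent[k], TRUE, FALSE, FALSE, k)
  for (k in 1:6) put(ids_latent[k], TRUE, FALSE, TRUE, k)

  family_tree <- list(
    lIFG = list(with = c(7, 8, 10:13, 15, 16, 18:21),
                without = c(1:6, 9, 14, 17)),
    interhemispheric = list(with = c(9, 17), without = c(1:6, 14)),
    rIFG_input = list(with = 14, without = 1:6))

  structure(list(models = models, family_tree = family_tree, nodes = nodes),
            class = "model_space")
}

#' Family partition at one level of the greedy search
#'
#' @param space A [build_model_space()] result.
#' @param level 1 (left-IFG), 2 (interhemispheric) or 3 (right-IFG latent
#'   input).
#' @return Named list of two disjoint model-id vectors (`with`, `without`).
#' @export
family_partition <- function(space, level) {
  if (!level %in% 1:3) stop("unknown family level: ", level)
  space$family_tree[[level]]
}

#' Serialize an architecture to its defining matrices
#'
#' @param arch A [network_architecture()].
#' @return List of matrices/vectors (`A_fwd`, `A_bwd`, `A_lat`, `C`,
#'   `latent`, `B_fwd`, `B_bwd`, `B_lat`, `B_self`, `model_id`).
#' @export
architecture_to_matrices <- function(arch) {
  arch[c("A_fwd", "A_bwd", "A_lat", "C", "latent",
         "B_fwd", "B_bwd", "B_lat", "B_self", "model_id")]
}

#' Write / read a model-space manifest (JSON)
#'
#' The manifest lists every model's matrices, input flags, modulation masks
#' and family tags; round-trips bit-exactly through [read_model_space()].
#' @param space A `model_space`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_space <- function(space, path) {
  ser <- list(
    nodes = space$nodes,
    family_tree = space$family_tree,
    models = lapply(space$models, function(a) {
      m <- architecture_to_matrices(a)
      m$mod_classes <- a$mod_classes
      m$reconstructed <- a$reconstructed
      m
    }))
  jsonlite::write_json(ser, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_space
#' @export
read_model_space <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- unlist(ser$nodes)
  n <- length(nodes)
  as_mat <- function(x) {
    m <- do.call(rbind, lapply(x, function(row) unlist(row)))
    matrix(as.numeric(m), n, n)
  }
  models <- lapply(ser$models, function(mo) {
    network_architecture(
      nodes = nodes,
      A_fwd = as_mat(mo$A_fwd), A_bwd = as_mat(mo$A_bwd),
      A_lat = as_mat(mo$A_lat),
      C = unlist(mo$C), latent = unlist(mo$latent),
      B_fwd = as_mat(mo$B_fwd), B_bwd = as_mat(mo$B_bwd),
      B_lat = as_mat(mo$B_lat),
      B_self = as.logical(unlist(mo$B_self)),
      model_id = mo$model_id[[1]],
      mod_classes = unlist(mo$mod_classes),
      reconstructed = isTRUE(mo$reconstructed[[1]]))
  })
  ft <- lapply(ser$family_tree, function(lv) lapply(lv, function(v) unlist(v)))
  structure(list(models = models, family_tree = ft, nodes = nodes),
            class = "model_space")
}
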
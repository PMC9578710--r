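#' Build a Hippo shuttling reaction network
#'
#' Constructs one of the two model topologies for nuclear/cytoplasmic
#' shuttling of a Hippo effector (YAP or TAZ). Both describe two forms of
#' the effector -- unphosphorylated `U` and phosphorylated `P` -- with
#' first-order kinetics throughout:
#'
#' * `"canonical"`: phosphorylation (`U -> P`) and dephosphorylation
#'   (`P -> U`) occur only in the cytoplasm; `P` is confined to the
#'   cytoplasm; `U` crosses the nuclear membrane in both directions
#'   (import and a first-order return flux).
#' * `"alternative"`: phosphorylation and dephosphorylation occur in the
#'   nucleus; `U` is imported into the nucleus, `P` is exported to the
#'   cytoplasm, where it is dephosphorylated back to `U`.
#'
#' Both topologies share a zeroth-order cytoplasmic synthesis of `U` and
#' first-order cytoplasmic degradation of both forms, so that a unique
#' nontrivial steady state exists whenever degradation is switched on.
#' The cell is closed: nothing crosses the plasma membrane.
#'
#' @param kind `"canonical"` or `"alternative"`.
#' @return An object of class `shuttle_network`: a list with elements
#'   `topology`, `species` (per-species allowed compartments),
#'   `volume_reactions`, `membrane_transports` and `synthesis`
#'   (data frames of symbolic reactions).
#' @examples
#' net <- shuttle_topology("alternative")
#' net$volume_reactions
#' @export
shuttle_topology <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("canonical", "alternative")) {
    stop("`kind` must be one of \"canonical\" or \"alternative\"",
         call. = FALSE)
  }
  species <- list(
    U = list(allowed = c("cytoplasm", "nucleus")),
    P = list(allowed = if (kind == "canonical") "cytoplasm"
             else c("cytoplasm", "nucleus"))
  )
  if (kind == "canonical") {
    vol <- data.frame(
      compartment = c("cytoplasm", "cytoplasm", "cytoplasm"),
      substrate   = c("U", "P", "U"),
      product     = c("P", "U", NA),
      rate        = c("k_phos", "k_dephos_cyt", "k_deg"),
      stringsAsFactors = FALSE
    )
    vol <- rbind(vol, data.frame(compartment = "cytoplasm", substrate = "P",
                                 product = NA, rate = "k_deg"))
    mem <- data.frame(
      membrane  = c("nuclear", "nuclear"),
      species   = c("U", "U"),
      direction = c("in", "out"),
      rate      = c("k_import", "k_export"),
      stringsAsFactors = FALSE
    )
  } else {
    vol <- data.frame(
      compartment = c("nucleus", "nucleus", "cytoplasm", "cytoplasm",
                      "cytoplasm"),
      substrate   = c("U", "P", "P", "U", "P"),
      product     = c("P", "U", "U", NA, NA),
      rate        = c("k_phos", "k_dephos_nuc", "k_dephos_cyt",
                      "k_deg", "k_deg"),
      stringsAsFactors = FALSE
    )
    mem <- data.frame(
      membrane  = c("nuclear", "nuclear"),
      species   = c("U", "P"),
      direction = c("in", "out"),
      rate      = c("k_import", "k_export"),
      stringsAsFactors = FALSE
    )
  }
  net <- structure(
    list(topology = kind,
         species = species,
         volume_reactions = vol,
         membrane_transports = mem,
         synthesis = list(compartment = "cytoplasm", species = "U",
                          rate = "k_syn")),
    class = "shuttle_network"
  )
  validate_network(net)
  net
}

#' Validate a shuttle network against its structural invariants
#'
#' Checks that every reaction's substrate and product are allowed in the
#' reaction's compartment, that the canonical topology has no nuclear
#' reactions and no nuclear `P`, and that no transport crosses the plasma
#' membrane.
#'
#' @param net A `shuttle_network`.
#' @return `net`, invisibly; errors if an invariant is violated.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "shuttle_network"))
  allowed <- function(sp, comp) comp %in% net$species[[sp]]$allowed
  vr <- net$volume_reactions
  for (k in seq_len(nrow(vr))) {
    if (!allowed(vr$substrate[k], vr$compartment[k]))
      stop("substrate ", vr$substrate[k], " not allowed in ",
           vr$compartment[k])
    if (!is.na(vr$product[k]) && !allowed(vr$product[k], vr$compartment[k]))
      stop("product ", vr$product[k], " not allowed in ", vr$compartment[k])
  }
  if (any(net$membrane_transports$membrane != "nuclear"))
    stop("transport across the plasma membrane is not part of either topology")
  if (net$topology == "canonical") {
    if (any(vr$compartment == "nucleus"))
      stop("canonical topology must have no nuclear reactions")
    if ("nucleus" %in% net$species$P$allowed)
      stop("canonical topology must confine P to the cytoplasm")
  }
  invisible(net)
}

#' @export
print.shuttle_network <- function(x, ...) {
  cat("Hippo shuttling network (", x$topology, " topology)\n", sep = "")
  cat("Species: U in {", paste(x$species$U$allowed, collapse = ", "),
      "}; P in {", paste(x$species$P$allowed, collapse = ", "), "}\n",
      sep = "")
  cat("Volume reactions:\n")
  print(x$volume_reactions, row.names = FALSE)
  cat("Nuclear-membrane transports:\n")
  print(x$membrane_transports, row.names = FALSE)
  cat("Synthesis: ", x$synthesis$rate, " -> ", x$synthesis$species,
      " (", x$synthesis$compartment, ")\n", sep = "")
  invisible(x)
}

#' Nuclear phosphorylation/dephosphorylation ratio
#'
#' The dimensionless ratio `r = k_phos / k_dephos_nuc` that governs
#' nuclear retention versus exclusion in the alternative topology.
#'
#' @param params A [shuttle_params()] object.
#' @return The ratio `r`.
#' @export
phospho_ratio <- function(params) {
  stopifnot(inherits(params, "shuttle_params"))
  if (params$k_dephos_nuc <= 0)
    stop("phosphorylation/dephosphorylation ratio undefined: ",
         "k_dephos_nuc must be > 0", call. = FALSE)
  params$k_phos / params$k_dephos_nuc
}

#' Serialize / deserialize a network to YAML
#'
#' @param net A `shuttle_network`.
#' @param path File to write to / read from.
#' @return `network_from_yaml` returns a validated `shuttle_network`.
#' @export
network_to_yaml <- function(net, path) {
  validate_network(net)
  obj <- list(
    topology = net$topology,
    species = lapply(net$species, function(s) list(allowed = s$allowed)),
    volume_reactions = lapply(seq_len(nrow(net$volume_reactions)),
                              function(i) as.list(net$volume_reactions[i, ])),
    membrane_transports = lapply(seq_len(nrow(net$membrane_transports)),
                                 function(i)
                                   as.list(net$membrane_transports[i, ])),
    synthesis = net$synthesis
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname network_to_yaml
#' @export
network_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  net <- structure(
    list(topology = obj$topology,
         species = lapply(obj$species, function(s)
           list(allowed = unlist(s$allowed))),
         volume_reactions = do.call(rbind, lapply(obj$volume_reactions,
           function(r) data.frame(compartment = r$compartment,
                                  substrate = r$substrate,
                                  product = if (is.null(r$product) ||
                                                is.na(r$product)) NA_character_
                                            else r$product,
                                  rate = r$rate,
                                  stringsAsFactors = FALSE))),
         membrane_transports = do.call(rbind, lapply(obj$membrane_transports,
           function(r) as.data.frame(r, stringsAsFactors = FALSE))),
         synthesis = obj$synthesis),
    class = "shuttle_network"
  )
  validate_network(net)
  net
}
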
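#' Define a network registry
#'
#' A network registry names the resting-state networks under study, the base
#' (unlateralized) atlas regions belonging to each, and the hemisphere scopes
#' at which connectivity is evaluated. Crossing networks with scopes yields
#' the *network configurations* over which intra- and inter-network
#' connectivity features are enumerated: `C` configurations give
#' `C + C*(C-1)/2` features.
#'
#' Regions may belong to several networks (e.g. a medial prefrontal region
#' shared by a motor and the default mode network); configurations are
#' instantiated per hemisphere scope, with the `both` scope treating left and
#' right instances as separate nodes.
#'
#' @param networks Named list mapping network name to a character vector of
#'   base region names.
#' @param scopes Character subset of `c("left", "right", "both")`, in the
#'   order configurations should be enumerated.
#' @param suffixes Named character vector with entries `left` and `right`
#'   giving the lateralization suffix appended to base region names.
#' @return An object of class `network_registry`.
#' @seealso [default_network_registry()], [network_configurations()],
#'   [feature_names()]
#' @export
#' @examples
#' reg <- network_registry(list(A = c("R1", "R2"), B = c("R3", "R4")))
#' length(network_configurations(reg))
network_registry <- function(networks,
                             scopes = c("left", "right", "both"),
                             suffixes = c(left = "_L", right = "_R")) {
  if (!is.list(networks) || is.null(names(networks)) ||
      any(!nzchar(names(networks)))) {
    abort("`networks` must be a named list of character vectors.")
  }
  if (anyDuplicated(names(networks))) {
    abort("Network names must be unique.")
  }
  scopes <- match.arg(scopes, c("left", "right", "both"), several.ok = TRUE)
  if (!all(c("left", "right") %in% names(suffixes))) {
    abort("`suffixes` needs entries named 'left' and 'right'.")
  }
  for (nm in names(networks)) {
    if (!is.character(networks[[nm]]) || length(networks[[nm]]) < 1) {
      abort(paste0("Network '", nm, "' must list at least one region."))
    }
  }
  structure(
    list(networks = networks, scopes = scopes, suffixes = suffixes),
    class = "network_registry"
  )
}

#' The default six-network registry
#'
#' Six predefined resting-state networks built from AAL3 atlas regions: four
#' motor-related networks (primary sensorimotor; premotor/prefrontal;
#' cingulo-insular; basal ganglia), the default mode network, and the
#' frontoparietal network. With the three hemisphere scopes this yields 18
#' network configurations and 171 connectivity features.
#'
#' @return A `network_registry`.
#' @export
#' @examples
#' reg <- default_network_registry()
#' length(feature_names(reg))
default_network_registry <- function() {
  network_registry(list(
    MotorI = c("PreCG", "PoCG", "PCL"),
    MotorII = c("SMA", "SFG", "MFG", "IFGoperc", "ROL", "SFGmedial"),
    MotorIII = c("INS", "ACCsup", "MCC"),
    MotorIV = c("PUT", "PAL", "CAU"),
    DMN = c("SFGmedial", "PCC", "ACCsub", "ACCpre", "ACCsup", "ANG", "PCUN"),
    Frontoparietal = c("MFG", "IFGoperc", "IFGtriang", "ANG", "IPG")
  ))
}

#' @export
print.network_registry <- function(x, ...) {
  cat("<network_registry>: ", length(x$networks), " networks x ",
      length(x$scopes), " scopes = ",
      length(x$networks) * length(x$scopes), " configurations\n", sep = "")
  for (nm in names(x$networks)) {
    cat("  ", nm, ": ", paste(x$networks[[nm]], collapse = ", "), "\n",
        sep = "")
  }
  cat("  scopes: ", paste(x$scopes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Base and lateralized region names of a registry
#'
#' @param registry A [network_registry()].
#' @return `base_regions()`: unique base region names in first-appearance
#'   order. `lateralized_regions()`: left and right instances of each base
#'   region (interleaved), the node set of the full connectivity analysis.
#' @export
base_regions <- function(registry) {
  stopifnot(inherits(registry, "network_registry"))
  unique(unlist(registry$networks, use.names = FALSE))
}

#' @rdname base_regions
#' @export
lateralized_regions <- function(registry) {
  base <- base_regions(registry)
  as.vector(rbind(
    paste0(base, registry$suffixes[["left"]]),
    paste0(base, registry$suffixes[["right"]])
  ))
}

lateralize <- function(registry, base, scope) {
  sfx <- registry$suffixes
  switch(scope,
    left = paste0(base, sfx[["left"]]),
    right = paste0(base, sfx[["right"]]),
    both = as.vector(rbind(paste0(base, sfx[["left"]]),
                           paste0(base, sfx[["right"]])))
  )
}

#' Enumerate network configurations
#'
#' Instantiates every network x hemisphere-scope combination of a registry in
#' canonical order: networks in registry order, scopes in registry scope
#' order. Each configuration carries its lateralized member regions; the
#' `both` scope takes the union of left and right instances as separate
#' nodes.
#'
#' @param registry A [network_registry()].
#' @return A list of configurations, each a list with elements `network`,
#'   `scope`, `label` (`"<network>:<scope>"`) and `members`.
#' @export
network_configurations <- function(registry) {
  stopifnot(inherits(registry, "network_registry"))
  out <- list()
  for (nm in names(registry$networks)) {
    for (sc in registry$scopes) {
      out[[length(out) + 1L]] <- list(
        network = nm,
        scope = sc,
        label = paste0(nm, ":", sc),
        members = lateralize(registry, registry$networks[[nm]], sc)
      )
    }
  }
  out
}

#' Canonical connectivity feature names
#'
#' All intra-network features (one per configuration, in configuration
#' order) followed by all inter-network features (one per unordered
#' configuration pair, pairs in configuration order). Feature names have the
#' forms `intra|<network>:<scope>` and
#' `inter|<netA>:<scopeA>|<netB>:<scopeB>`.
#'
#' @param registry A [network_registry()].
#' @return Character vector of length `C + C*(C-1)/2` where `C` is the
#'   number of configurations.
#' @export
feature_names <- function(registry) {
  cfg <- network_configurations(registry)
  labels <- map_chr(cfg, "label")
  intra <- paste0("intra|", labels)
  inter <- character(0)
  C <- length(labels)
  if (C >= 2) {
    for (i in seq_len(C - 1)) {
      for (j in seq(i + 1, C)) {
        inter <- c(inter, paste0("inter|", labels[i], "|", labels[j]))
      }
    }
  }
  c(intra, inter)
}

#' Parse a connectivity feature name
#'
#' @param name Feature name such as `"intra|MotorI:left"` or
#'   `"inter|MotorI:both|MotorIV:left"`.
#' @return A list with `type` (`"intra"` or `"inter"`) and `scopes`
#'   (character vector of the one or two hemisphere scopes involved), plus
#'   `networks`.
#' @export
parse_feature_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  bad <- function() {
    abort(paste0("Unparseable connectivity feature name: '", name, "'"))
  }
  if (length(parts) < 2 || !parts[1] %in% c("intra", "inter")) bad()
  if (parts[1] == "intra" && length(parts) != 2) bad()
  if (parts[1] == "inter" && length(parts) != 3) bad()
  cfgs <- strsplit(parts[-1], ":", fixed = TRUE)
  if (any(lengths(cfgs) != 2)) bad()
  scopes <- map_chr(cfgs, 2)
  if (!all(scopes %in% c("left", "right", "both"))) bad()
  list(type = parts[1], networks = map_chr(cfgs, 1), scopes = scopes)
}

#' Read a network registry from a YAML file
#'
#' The file must define a `networks` mapping (network name to list of base
#' region names) and may override `scopes` and `suffixes`.
#'
#' @param path Path to a YAML file.
#' @return A [network_registry()].
#' @export
read_network_registry <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$networks)) abort("Registry YAML must define `networks`.")
  networks <- map(spec$networks, as.character)
  scopes <- spec$scopes %||% c("left", "right", "both")
  suffixes <- c(left = "_L", right = "_R")
  if (!is.null(spec$suffixes)) {
    suffixes <- c(left = spec$suffixes$left, right = spec$suffixes$right)
  }
  network_registry(networks, scopes = scopes, suffixes = suffixes)
}
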
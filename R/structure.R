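#' Ordered C-alpha structure
#'
#' Container for the native structure r0 used by all downstream matrices: an
#' ordered set of residue sites, one coordinate triple per site. Site order is
#' fixed at construction and preserved by every matrix built from it.
#'
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param site_ids character vector of residue identifiers
#'   (`"<chain>:<resno><icode>"`); defaults to `"A:1"`, `"A:2"`, ...
#' @return An object of class `ca_structure` with fields `site_ids`, `coords`
#'   and `n_sites`.
#' @examples
#' s <- ca_structure(matrix(rnorm(15), 5, 3))
#' s$n_sites
#' @export
ca_structure <- function(coords, site_ids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 2L || !all(is.finite(coords))) {
    mrscan_error("invalid_parameter",
                 "coords must be a finite N x 3 matrix with N >= 2")
  }
  n <- nrow(coords)
  if (is.null(site_ids)) site_ids <- paste0("A:", seq_len(n))
  if (length(site_ids) != n) {
    mrscan_error("inconsistent_inputs", "one site_id per coordinate row")
  }
  dimnames(coords) <- list(site_ids, c("x", "y", "z"))
  structure(list(site_ids = as.character(site_ids), coords = coords,
                 n_sites = n),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("C-alpha structure: %d sites (%s ... %s)\n",
              x$n_sites, x$site_ids[1L], x$site_ids[x$n_sites]))
  invisible(x)
}

#' Parse C-alpha records from PDB text
#'
#' Reads `ATOM` records with atom name `CA` from PDB-format text and returns
#' them in file order, one site per residue. `HETATM` and non-CA atoms are
#' ignored. Alternate locations keep the highest-occupancy record (ties broken
#' by altloc identifier order); insertion codes are preserved in the site ids.
#' Multiple chains are concatenated in file order unless `chain` is given.
#'
#' @param pdb_text character: PDB-format content, either a single string or a
#'   vector of lines; alternatively a file path to read.
#' @param chain optional single chain identifier to select.
#' @param model model number to use when the file has `MODEL` records
#'   (default 1 = first model).
#' @return A [ca_structure()].
#' @examples
#' txt <- write_fixture_pdb(generate_helix(5))
#' parse_ca_structure(txt)
#' @export
parse_ca_structure <- function(pdb_text, chain = NULL, model = 1L) {
  lines <- if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
               file.exists(pdb_text)) {
    readLines(pdb_text, warn = FALSE)
  } else {
    unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  }

  rec <- substr(lines, 1L, 6L)
  # assign a model number to every line: 1 before any MODEL record
  model_no <- cumsum(rec == "MODEL ")
  model_no[model_no == 0L] <- 1L
  n_models <- max(model_no)
  if (model > n_models) {
    mrscan_error("invalid_parameter",
                 sprintf("model %d requested but file has %d model(s)",
                         model, n_models))
  }
  keep <- rec == "ATOM  " & model_no == model
  atom <- lines[keep]
  name <- trimws(substr(atom, 13L, 16L))
  atom <- atom[name == "CA"]

  chains_present <- unique(substr(atom, 22L, 22L))
  if (!is.null(chain)) {
    if (!(chain %in% chains_present)) {
      mrscan_error("chain_not_found",
                   sprintf("chain '%s' not found (present: %s)", chain,
                           paste(chains_present, collapse = ", ")))
    }
    atom <- atom[substr(atom, 22L, 22L) == chain]
  }
  if (length(atom) == 0L) {
    mrscan_error("empty_structure", "no C-alpha ATOM records found")
  }

  altloc <- substr(atom, 17L, 17L)
  reskey <- paste0(substr(atom, 22L, 22L), ":",
                   trimws(substr(atom, 23L, 26L)),
                   trimws(substr(atom, 27L, 27L)))
  occ <- suppressWarnings(as.numeric(substr(atom, 55L, 60L)))
  occ[is.na(occ)] <- 1

  # one record per residue: highest occupancy, ties by altloc order
  ord <- order(match(reskey, unique(reskey)), -occ, altloc)
  first <- !duplicated(reskey[ord])
  sel <- ord[first]
  sel <- sel[order(sel)]  # restore file order of the chosen records
  atom <- atom[sel]

  coords <- cbind(as.numeric(substr(atom, 31L, 38L)),
                  as.numeric(substr(atom, 39L, 46L)),
                  as.numeric(substr(atom, 47L, 54L)))
  if (anyNA(coords)) {
    mrscan_error("invalid_parameter", "malformed coordinate fields")
  }
  if (nrow(coords) < 2L) {
    mrscan_error("empty_structure",
                 "fewer than 2 C-alpha sites in the selection")
  }
  ca_structure(coords, site_ids = reskey[sel])
}

#' Write a structure summary table
#'
#' Writes a delimited text summary with one row per site: site id,
#' coordinates and contact number under the topology's cutoff.
#'
#' @param structure a [ca_structure()].
#' @param topology a [build_contacts()] result for the same structure.
#' @param path output file path (TSV).
#' @return The path, invisibly.
#' @export
write_structure_summary <- function(structure, topology, path) {
  if (topology$n_sites != structure$n_sites) {
    mrscan_error("inconsistent_inputs",
                 "topology and structure have different site counts")
  }
  df <- data.frame(site_id = structure$site_ids,
                   x = structure$coords[, 1L],
                   y = structure$coords[, 2L],
                   z = structure$coords[, 3L],
                   CN = topology$cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
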
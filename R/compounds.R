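#' Annotated compound collections
#'
#' A `CompoundSet` holds a collection of annotated molecules: each compound
#' has a unique id, a structure (canonical SMILES plus a parsed connection
#' table), a class and subclass label, a set of fragment tags describing the
#' natural-product fragments it was assembled from, and a role. Fragment tags
#' are assigned by synthesis provenance (declared annotation), not perceived
#' by substructure matching.
#'
#' Roles distinguish the pseudo-natural products themselves (`"pnp"`, always
#' carrying exactly two fragment tags), the guiding fragment-sized natural
#' products (`"guiding_np"`), small combination fragments
#' (`"small_fragment"`), and predictively designed classes
#' (`"predicted_class"`).
#'
#' @param compounds data.frame with columns `id`, `smiles`, `class_label`,
#'   `subclass_label`, `fragments` (semicolon-separated tags), `role`.
#' @param provenance free-text description of where the collection came from.
#' @return An object of class `CompoundSet`: a list with elements
#'   `compounds` (the annotation table, with canonicalized SMILES), `mols`
#'   (named list of parsed SDF connection tables), `errors` (per-record parse
#'   failures) and `provenance`.
#' @export
compound_set <- function(compounds, provenance = "") {
  required <- c("id", "smiles", "class_label", "subclass_label",
                "fragments", "role")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols)) {
    stopf("compound table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  compounds <- as.data.frame(compounds)[required]
  for (col in required) compounds[[col]] <- as.character(compounds[[col]])
  if (nrow(compounds) == 0L) stopf("compound set must be non-empty")

  dup <- unique(compounds$id[duplicated(compounds$id)])
  if (length(dup)) {
    stopf("duplicate compound id(s): %s", paste(dup, collapse = ", "))
  }

  can <- canonical_smiles(compounds$smiles)
  bad <- which(is.na(can))
  errors <- data.frame(
    record = bad,
    id = compounds$id[bad],
    reason = rep("unparseable structure", length(bad)),
    stringsAsFactors = FALSE
  )
  ok <- setdiff(seq_len(nrow(compounds)), bad)
  compounds$smiles[ok] <- can[ok]
  parsed <- compounds[ok, , drop = FALSE]
  mols <- smiles_to_sdf(parsed$smiles, ids = parsed$id)

  structure(
    list(compounds = parsed, mols = mols, errors = errors,
         provenance = provenance),
    class = "CompoundSet"
  )
}

#' @export
print.CompoundSet <- function(x, ...) {
  cat(sprintf("CompoundSet: %d compounds (%d parse failures)\n",
              nrow(x$compounds), nrow(x$errors)))
  cat(sprintf("  classes: %s\n",
              paste(unique(x$compounds$class_label), collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.CompoundSet <- function(x) nrow(x$compounds)

#' Read an annotated compound collection
#'
#' Reads a SMILES-in-CSV table (columns `id`, `smiles`, `class`, `subclass`,
#' `fragments` semicolon-separated, `role`) or an SDF file carrying the same
#' annotations as SD tags. Structures are parsed and canonicalized with
#' OpenBabel; records that fail to parse are collected in the `errors`
#' element of the result rather than silently dropped, so that
#' `parsed + failed = input records` always holds.
#'
#' @param path file to read.
#' @param format `"smiles_csv"` or `"sdf"`.
#' @return A [compound_set()] object.
#' @export
read_compounds <- function(path, format = c("smiles_csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)

  if (format == "smiles_csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    alias <- c(class = "class_label", subclass = "subclass_label")
    for (a in names(alias)) {
      if (a %in% names(df) && !(alias[[a]] %in% names(df))) {
        names(df)[names(df) == a] <- alias[[a]]
      }
    }
    compound_set(df, provenance = path)
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    blocks <- ChemmineR::datablock(sdfset)
    get_tag <- function(b, tag) {
      if (tag %in% names(b)) as.character(b[[tag]]) else ""
    }
    rows <- lapply(seq_along(sdfset), function(i) {
      b <- as.list(blocks[[i]])
      data.frame(
        id = get_tag(b, "id"),
        smiles = as.character(ChemmineR::sdf2smiles(sdfset[i])),
        class_label = get_tag(b, "class"),
        subclass_label = get_tag(b, "subclass"),
        fragments = get_tag(b, "fragments"),
        role = get_tag(b, "role"),
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
    compound_set(df, provenance = path)
  }
}

#' Write a compound collection as normalized CSV
#'
#' @param set a [compound_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(set, path) {
  stopifnot(inherits(set, "CompoundSet"))
  df <- set$compounds
  names(df) <- c("id", "smiles", "class", "subclass", "fragments", "role")
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate a compound collection
#'
#' Checks the collection invariants: unique parseable structures, at least
#' one fragment tag per compound, exactly two fragment tags for PNPs, a
#' consistent (injective into classes) subclass-to-class mapping, known
#' roles, and optionally that labels are drawn from a declared vocabulary.
#'
#' @param set a [compound_set()].
#' @param vocabulary optional list with character vectors `classes`,
#'   `subclasses`, `fragments` declaring the allowed labels.
#' @return data.frame with columns `rule`, `id`, `message`; zero rows iff
#'   all invariants hold.
#' @export
validate_collection <- function(set, vocabulary = NULL) {
  stopifnot(inherits(set, "CompoundSet"))
  df <- set$compounds
  out <- list()
  add <- function(rule, id, message) {
    out[[length(out) + 1L]] <<- data.frame(
      rule = rule, id = id, message = message, stringsAsFactors = FALSE
    )
  }

  if (nrow(set$errors)) {
    for (i in seq_len(nrow(set$errors))) {
      add("structure", set$errors$id[i], set$errors$reason[i])
    }
  }

  frag_list <- lapply(df$fragments, split_tags)
  nfrag <- vapply(frag_list, length, integer(1))
  for (i in which(nfrag < 1L)) {
    add("fragments", df$id[i], "compound has no fragment tags")
  }
  for (i in which(df$role == "pnp" & nfrag != 2L)) {
    add("fragments", df$id[i],
        sprintf("PNP must have exactly 2 fragment tags (has %d)", nfrag[i]))
  }

  known_roles <- c("pnp", "guiding_np", "small_fragment", "predicted_class")
  for (i in which(!(df$role %in% known_roles))) {
    add("role", df$id[i], sprintf("unknown role '%s'", df$role[i]))
  }

  # subclass -> class must be single-valued
  map <- unique(df[, c("subclass_label", "class_label")])
  dup_sub <- unique(map$subclass_label[duplicated(map$subclass_label)])
  for (s in dup_sub) {
    cls <- map$class_label[map$subclass_label == s]
    add("subclass_map", s,
        sprintf("subclass '%s' mapped to multiple classes: %s",
                s, paste(cls, collapse = ", ")))
  }

  if (!is.null(vocabulary)) {
    check_vocab <- function(values, allowed, rule) {
      for (i in which(!(values %in% allowed))) {
        add(rule, df$id[i], sprintf("label '%s' not in vocabulary", values[i]))
      }
    }
    if (!is.null(vocabulary$classes)) {
      check_vocab(df$class_label, vocabulary$classes, "vocabulary_class")
    }
    if (!is.null(vocabulary$subclasses)) {
      check_vocab(df$subclass_label, vocabulary$subclasses,
                  "vocabulary_subclass")
    }
    if (!is.null(vocabulary$fragments)) {
      for (i in seq_along(frag_list)) {
        unknown <- setdiff(frag_list[[i]], vocabulary$fragments)
        if (length(unknown)) {
          add("vocabulary_fragment", df$id[i],
              sprintf("fragment tag(s) not in vocabulary: %s",
                      paste(unknown, collapse = ", ")))
        }
      }
    }
  }

  if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(rule = character(0), id = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
}

# fragment tags per compound as a named list
compound_fragments <- function(set) {
  setNames(lapply(set$compounds$fragments, split_tags), set$compounds$id)
}
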
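#' Read a structure from PDB or mmCIF
#'
#' Fixed-column PDB coordinate records (`ATOM`/`HETATM`), anisotropic ADP
#' records (`ANISOU`, cartesian U x 1e4) and the `CRYST1` cell/symmetry
#' header are supported, plus a documented mmCIF subset (`_cell`,
#' `_symmetry`, `atom_site` and `atom_site_anisotrop` loops). Fractional
#' coordinates are derived from the cell; `ANISOU` tensors are matched to
#' their atom by serial number.
#'
#' @param path File path.
#' @param dialect `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return A [xtal_structure()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (dialect == "pdb") read_pdb(path) else read_mmcif(path)
}

parse_pdb_num <- function(txt, lineno, what) {
  out <- suppressWarnings(as.numeric(txt))
  if (anyNA(out)) {
    stop("malformed ", what, " field at line ", lineno[which(is.na(out))[1]],
         call. = FALSE)
  }
  out
}

read_pdb_atoms <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (!length(idx)) stop("no coordinate records found", call. = FALSE)
  al <- lines[idx]
  f <- function(from, to) trimws(substr(al, from, to))
  atoms <- tibble::tibble(
    record = trimws(substr(al, 1, 6)),
    serial = as.integer(f(7, 11)),
    name = f(13, 16),
    altloc = trimws(substr(al, 17, 17)),
    resname = f(18, 20),
    chain = trimws(substr(al, 22, 22)),
    resid = as.integer(f(23, 26)),
    x = parse_pdb_num(f(31, 38), idx, "x coordinate"),
    y = parse_pdb_num(f(39, 46), idx, "y coordinate"),
    z = parse_pdb_num(f(47, 54), idx, "z coordinate"),
    occ = parse_pdb_num(f(55, 60), idx, "occupancy"),
    b = parse_pdb_num(f(61, 66), idx, "B factor"),
    element = f(77, 78)
  )
  atoms$element[atoms$element == ""] <- substr(atoms$name[atoms$element == ""], 1, 1)
  atoms
}

read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("missing CRYST1 record", call. = FALSE)
  cr <- cr[1]
  cell <- unit_cell(
    as.numeric(substr(cr, 7, 15)), as.numeric(substr(cr, 16, 24)),
    as.numeric(substr(cr, 25, 33)), as.numeric(substr(cr, 34, 40)),
    as.numeric(substr(cr, 41, 47)), as.numeric(substr(cr, 48, 54))
  )
  sg <- spacegroup(trimws(substr(cr, 56, 66)))
  atoms <- read_pdb_atoms(lines)

  frac <- cart_to_frac(cell, as.matrix(atoms[, c("x", "y", "z")]))
  u <- u_from_biso(atoms$b)
  out <- tibble::tibble(
    record = atoms$record, chain = atoms$chain, resid = atoms$resid,
    resname = atoms$resname, name = atoms$name, altloc = atoms$altloc,
    element = atoms$element,
    fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
    occ = atoms$occ, u, aniso = FALSE
  )

  au <- grep("^ANISOU", lines)
  if (length(au)) {
    aserial <- as.integer(trimws(substr(lines[au], 7, 11)))
    pos <- match(aserial, atoms$serial)
    if (anyNA(pos)) {
      stop("ANISOU record without matching atom at line ", au[which(is.na(pos))[1]],
           call. = FALSE)
    }
    vals <- vapply(c(29, 36, 43, 50, 57, 64), function(from) {
      parse_pdb_num(trimws(substr(lines[au], from, from + 6)), au, "ANISOU")
    }, numeric(length(au))) / 1e4
    if (length(au) == 1) vals <- matrix(vals, nrow = 1)
    out$u11[pos] <- vals[, 1]; out$u22[pos] <- vals[, 2]; out$u33[pos] <- vals[, 3]
    out$u12[pos] <- vals[, 4]; out$u13[pos] <- vals[, 5]; out$u23[pos] <- vals[, 6]
    out$aniso[pos] <- TRUE
  }
  xtal_structure(cell, sg, out)
}

#' Write a structure as PDB
#'
#' Emits `CRYST1`, fixed-column `ATOM`/`HETATM` records (cartesian
#' coordinates, derived isotropic B) and `ANISOU` records for atoms with
#' genuine anisotropic tensors. Output is byte-deterministic for a given
#' structure.
#'
#' @param s A [xtal_structure()].
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_structure <- function(s, path) {
  writeLines(format_pdb(s), path)
  invisible(path)
}

format_pdb <- function(s, model = NULL) {
  cl <- s$cell
  lines <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
    cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
    format_sg_symbol(s$spacegroup$symbol), 1L
  )
  a <- s$atoms
  cart <- atoms_cart(s)
  b <- biso(s)
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  name4 <- formatC(name4, width = -4)
  chain1 <- substr(ifelse(a$chain == "", "A", a$chain), 1, 1)
  rec <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, seq_len(nrow(a)), name4, a$altloc, a$resname, chain1, a$resid,
    cart[, 1], cart[, 2], cart[, 3], a$occ, b, toupper(a$element)
  )
  ani <- which(a$aniso)
  if (length(ani)) {
    arec <- sprintf(
      "ANISOU%5d %-4s%1s%-3s %1s%4d  %7d%7d%7d%7d%7d%7d      %2s",
      ani, name4[ani], a$altloc[ani], a$resname[ani], chain1[ani], a$resid[ani],
      round(a$u11[ani] * 1e4), round(a$u22[ani] * 1e4), round(a$u33[ani] * 1e4),
      round(a$u12[ani] * 1e4), round(a$u13[ani] * 1e4), round(a$u23[ani] * 1e4),
      toupper(a$element[ani])
    )
    # interleave each ANISOU directly after its atom record
    ord <- order(c(seq_along(rec), ani + 0.5))
    body <- c(rec, arec)[ord]
  } else {
    body <- rec
  }
  if (!is.null(model)) {
    body <- c(sprintf("MODEL     %4d", model), body, "ENDMDL")
  }
  c(lines, body, if (is.null(model)) "END")
}

format_sg_symbol <- function(symbol) {
  # "C2" -> "C 1 2 1" style H-M; keep P1/C2 family readable
  switch(symbol,
    "P1" = "P 1", "P2" = "P 1 2 1", "P21" = "P 1 21 1", "C2" = "C 1 2 1",
    symbol
  )
}

parse_sg_symbol <- function(text) {
  key <- toupper(gsub("[[:space:]]", "", text))
  switch(key,
    "P1" = "P1",
    "C2" = , "C121" = "C2",
    "P2" = , "P121" = "P2",
    "P21" = , "P1211" = "P21",
    key
  )
}

# ---- mmCIF subset ----------------------------------------------------------

cif_tokens <- function(line) {
  # whitespace-separated tokens honouring single/double quotes
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)[[1]]
  if (m[1] == -1) return(character())
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

cif_value <- function(lines, tag) {
  hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  cif_tokens(hit[1])[2]
}

cif_loop <- function(lines, prefix) {
  starts <- grep("^loop_", lines)
  for (s0 in starts) {
    i <- s0 + 1
    tags <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!length(tags) || !all(startsWith(tags, prefix))) next
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "_") || startsWith(ln, "loop_") ||
          startsWith(ln, "#") || startsWith(ln, "data_")) break
      rows[[length(rows) + 1]] <- cif_tokens(ln)
      i <- i + 1
    }
    if (!length(rows)) next
    mat <- do.call(rbind, rows)
    colnames(mat) <- sub(paste0("^", prefix), "", tags)
    return(tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE)))
  }
  NULL
}

read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cell <- unit_cell(
    as.numeric(cif_value(lines, "_cell.length_a")),
    as.numeric(cif_value(lines, "_cell.length_b")),
    as.numeric(cif_value(lines, "_cell.length_c")),
    as.numeric(cif_value(lines, "_cell.angle_alpha")),
    as.numeric(cif_value(lines, "_cell.angle_beta")),
    as.numeric(cif_value(lines, "_cell.angle_gamma"))
  )
  sg_txt <- cif_value(lines, "_symmetry.space_group_name_H-M")
  sg <- spacegroup(if (is.na(sg_txt)) "P1" else parse_sg_symbol(sg_txt))
  at <- cif_loop(lines, "_atom_site.")
  if (is.null(at)) stop("no atom_site loop found in ", path, call. = FALSE)
  need <- c("group_PDB", "auth_asym_id", "auth_seq_id", "auth_comp_id",
            "label_atom_id", "label_alt_id", "type_symbol",
            "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv")
  missing <- setdiff(need, names(at))
  if (length(missing)) {
    stop("atom_site loop missing item(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cart <- cbind(as.numeric(at$Cartn_x), as.numeric(at$Cartn_y),
                as.numeric(at$Cartn_z))
  frac <- cart_to_frac(cell, cart)
  altloc <- at$label_alt_id
  altloc[altloc %in% c(".", "?")] <- ""
  atoms <- tibble::tibble(
    record = at$group_PDB, chain = at$auth_asym_id,
    resid = as.integer(at$auth_seq_id), resname = at$auth_comp_id,
    name = at$label_atom_id, altloc = altloc, element = at$type_symbol,
    fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
    occ = as.numeric(at$occupancy),
    u_from_biso(as.numeric(at$B_iso_or_equiv)), aniso = FALSE
  )
  if ("id" %in% names(at)) {
    ani <- cif_loop(lines, "_atom_site_anisotrop.")
    if (!is.null(ani)) {
      pos <- match(ani$id, at$id)
      if (anyNA(pos)) stop("anisotrop record without matching atom", call. = FALSE)
      atoms$u11[pos] <- as.numeric(ani$`U[1][1]`)
      atoms$u22[pos] <- as.numeric(ani$`U[2][2]`)
      atoms$u33[pos] <- as.numeric(ani$`U[3][3]`)
      atoms$u12[pos] <- as.numeric(ani$`U[1][2]`)
      atoms$u13[pos] <- as.numeric(ani$`U[1][3]`)
      atoms$u23[pos] <- as.numeric(ani$`U[2][3]`)
      atoms$aniso[pos] <- TRUE
    }
  }
  xtal_structure(cell, sg, atoms)
}

# ---- multi-model PDB (ensembles) ------------------------------------------

#' Write a multi-frame ensemble as a multi-model PDB
#'
#' @param ens A `supercell_frames` object from [make_ensemble()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "supercell_frames"))
  out <- character()
  s <- ens$base
  for (k in seq_along(ens$frames)) {
    s$atoms$fx <- ens$frames[[k]][, 1]
    s$atoms$fy <- ens$frames[[k]][, 2]
    s$atoms$fz <- ens$frames[[k]][, 3]
    lines <- format_pdb(s, model = k)
    out <- c(out, if (k == 1) lines else lines[-1])
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a multi-model PDB as an ensemble
#'
#' @param path File path.
#' @return A `supercell_frames` object: the first model as `base` plus one
#'   fractional coordinate matrix per model.
#' @export
read_ensemble_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    s <- read_pdb(path)
    return(new_supercell_frames(s, dims = c(1, 1, 1),
                                frames = list(as.matrix(s$atoms[, c("fx", "fy", "fz")]))))
  }
  ends <- grep("^ENDMDL", lines)
  header <- lines[seq_len(starts[1] - 1)]
  base <- NULL
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- c(header, lines[(starts[k] + 1):(ends[k] - 1)])
    tmp <- tempfile(fileext = ".pdb")
    writeLines(block, tmp)
    s <- read_pdb(tmp)
    unlink(tmp)
    if (is.null(base)) base <- s
    frames[[k]] <- as.matrix(s$atoms[, c("fx", "fy", "fz")])
  }
  new_supercell_frames(base, dims = c(1, 1, 1), frames = frames)
}
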
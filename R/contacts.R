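## donor/acceptor dictionary for the hydrogen-free hydrogen-bond criterion;
## antecedent atom supplies the donor-antecedent-donor-acceptor angle check
.hb_donors <- list(
  "*"   = list(c("N", "CA")),
  SER = list(c("OG", "CB")),   THR = list(c("OG1", "CB")),
  TYR = list(c("OH", "CZ")),   CYS = list(c("SG", "CB")),
  ASN = list(c("ND2", "CG")),  GLN = list(c("NE2", "CD")),
  LYS = list(c("NZ", "CE")),
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  HIS = list(c("ND1", "CG"), c("NE2", "CD2")),
  TRP = list(c("NE1", "CD1")))

.hb_acceptors <- list(
  "*"   = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD")

.salt_acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.salt_basic  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))

.bb_atoms <- c("N", "CA", "C", "O", "OXT")

atom_flags <- function(a) {
  don <- ant <- rep(NA_character_, nrow(a))
  is_don <- rep(FALSE, nrow(a)); is_acc <- rep(FALSE, nrow(a))
  acidic <- basic <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(a))) {
    res <- a$resid[i]; nm <- a$elety[i]
    for (set in c("*", res)) {
      dl <- .hb_donors[[set]]
      if (!is.null(dl)) for (dpair in dl) if (dpair[1] == nm) {
        is_don[i] <- TRUE; ant[i] <- dpair[2]
      }
      al <- .hb_acceptors[[set]]
      if (!is.null(al) && nm %in% al) is_acc[i] <- TRUE
    }
    if (!is.null(.salt_acidic[[res]]) && nm %in% .salt_acidic[[res]]) acidic[i] <- TRUE
    if (!is.null(.salt_basic[[res]]) && nm %in% .salt_basic[[res]]) basic[i] <- TRUE
  }
  data.frame(is_donor = is_don, antecedent = ant, is_acceptor = is_acc,
             acidic = acidic, basic = basic,
             moiety = ifelse(a$elety %in% .bb_atoms, "BB", "SC"),
             stringsAsFactors = FALSE)
}

## position of a named atom within the same residue as row i of table a
antecedent_pos <- function(a, i, name) {
  j <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
             a$icode == a$icode[i] & a$elety == name)
  if (length(j) == 0) return(NULL)
  as.numeric(a[j[1], c("x", "y", "z")])
}

#' Enumerate and classify receptor/ligand atomic contacts
#'
#' Inter-chain heavy-atom pairs are classified with field-standard geometric
#' criteria: van der Waals contact at <= `vdw_cutoff`; hydrogen bond for a
#' donor/acceptor heavy-atom pair at <= `hbond_cutoff` with an
#' antecedent-donor-acceptor angle >= 90 degrees (hydrogen-free criterion);
#' salt bridge for Asp/Glu side-chain oxygen against Lys NZ, Arg NE/NH1/NH2
#' or His ND1/NE2 at <= `salt_cutoff`.  Each pair is reported once under its
#' most specific class (salt > hbond > vdw).
#'
#' @param receptor,ligand [eph_structure] selections; hydrogens, waters and
#'   heteroatoms are excluded.
#' @param vdw_cutoff,hbond_cutoff,salt_cutoff Distance cutoffs in Angstrom.
#' @return A data frame of contact records: ligand residue/atom/moiety,
#'   receptor residue/atom/moiety, `distance`, `contact_class`.
#' @export
enumerate_contacts <- function(receptor, ligand, vdw_cutoff = 4.0,
                               hbond_cutoff = 3.5, salt_cutoff = 4.0) {
  prep <- function(s) {
    a <- s$atoms[!s$atoms$het & toupper(s$atoms$elesy) != "H", , drop = FALSE]
    if (nrow(a) == 0) stop("empty chain selection")
    cbind(a, atom_flags(a))
  }
  ra <- prep(receptor); la <- prep(ligand)
  rx <- as.matrix(ra[, c("x", "y", "z")]); lx <- as.matrix(la[, c("x", "y", "z")])
  maxcut <- max(vdw_cutoff, hbond_cutoff, salt_cutoff)
  out <- list()
  for (i in seq_len(nrow(la))) {
    d2 <- (rx[, 1] - lx[i, 1])^2 + (rx[, 2] - lx[i, 2])^2 + (rx[, 3] - lx[i, 3])^2
    hits <- which(d2 <= maxcut^2)
    for (j in hits) {
      d <- sqrt(d2[j])
      cls <- NA_character_
      if (d <= vdw_cutoff) cls <- "vdw"
      ## hydrogen bond, either direction
      hb <- FALSE
      if (d <= hbond_cutoff) {
        if (la$is_donor[i] && ra$is_acceptor[j]) {
          ap <- antecedent_pos(la, i, la$antecedent[i])
          if (!is.null(ap) &&
              three_atom_angle(ap, lx[i, ], rx[j, ]) >= 90) hb <- TRUE
        }
        if (!hb && ra$is_donor[j] && la$is_acceptor[i]) {
          ap <- antecedent_pos(ra, j, ra$antecedent[j])
          if (!is.null(ap) &&
              three_atom_angle(ap, rx[j, ], lx[i, ]) >= 90) hb <- TRUE
        }
      }
      if (hb) cls <- "hbond"
      if (d <= salt_cutoff &&
          ((la$acidic[i] && ra$basic[j]) || (la$basic[i] && ra$acidic[j])))
        cls <- "salt"
      if (!is.na(cls))
        out[[length(out) + 1L]] <- data.frame(
          ligand_res = sprintf("%s%d%s", la$resid[i], la$resno[i], la$icode[i]),
          ligand_resno = la$resno[i], ligand_atom = la$elety[i],
          ligand_moiety = la$moiety[i],
          receptor_res = sprintf("%s%d%s", ra$resid[j], ra$resno[j], ra$icode[j]),
          receptor_resno = ra$resno[j], receptor_atom = ra$elety[j],
          receptor_moiety = ra$moiety[j],
          distance = d, contact_class = cls, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(ligand_res = character(), ligand_resno = integer(),
                      ligand_atom = character(), ligand_moiety = character(),
                      receptor_res = character(), receptor_resno = integer(),
                      receptor_atom = character(), receptor_moiety = character(),
                      distance = numeric(), contact_class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarise contacts per ligand residue (published contact-table layout)
#'
#' Groups contact records by ligand residue and lists the receptor partners
#' with backbone/side-chain tags and class markers; rows from the ephrin GH
#' loop (ligand residues `gh_loop[1]`-`gh_loop[2]`) are separated from the
#' rest, mirroring the layout of published Eph/ephrin contact tables.
#'
#' @param contacts Output of [enumerate_contacts()].
#' @param gh_loop Length-2 residue-number range defining the GH loop
#'   (ephrin-A5: 121-129).
#' @return A data frame: `ligand_res`, `in_gh_loop`, `n_contacts`,
#'   `n_hbond`, `n_salt`, `receptor_partners` (collapsed string).
#' @export
residue_contact_summary <- function(contacts, gh_loop = c(121, 129)) {
  if (nrow(contacts) == 0)
    return(data.frame(ligand_res = character(), in_gh_loop = logical(),
                      n_contacts = integer(), n_hbond = integer(),
                      n_salt = integer(), receptor_partners = character(),
                      stringsAsFactors = FALSE))
  mark <- c(vdw = "", hbond = "*", salt = "**")
  rows <- lapply(split(contacts, contacts$ligand_res), function(g) {
    partners <- unique(sprintf("%s(%s)%s", g$receptor_res, g$receptor_moiety,
                               mark[g$contact_class]))
    data.frame(ligand_res = g$ligand_res[1], ligand_resno = g$ligand_resno[1],
               in_gh_loop = g$ligand_resno[1] >= gh_loop[1] &
                 g$ligand_resno[1] <= gh_loop[2],
               n_contacts = nrow(g),
               n_hbond = sum(g$contact_class == "hbond"),
               n_salt = sum(g$contact_class == "salt"),
               receptor_partners = paste(partners, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$in_gh_loop, out$ligand_resno), ]
  rownames(out) <- NULL
  out
}
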
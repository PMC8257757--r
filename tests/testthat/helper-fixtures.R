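## Shared fixtures: toy conformers are deterministic, build them once.

toyIn242 <- genToyStructure("in242")
toyIn244 <- genToyStructure("in244")
toyApo <- genToyStructure("apo")

toyBase <- function(model) selectResidue(model, "B", 6)

## apply a rigid transform (rotation matrix R, translation t) to a model
applyRigidModel <- function(model, R, t = c(0, 0, 0)) {
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  NeilTriage:::.newStructureModel(model@identifier, a)
}

rotZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

## small custom model builder for oracle tests: a bare ARG side chain and a
## pyrimidine-like base at arbitrary coordinates
makePairModel <- function(argCoords, baseCoords) {
  row <- NeilTriage:::.atomRow
  rows <- list()
  for (nm in rownames(argCoords))
    rows[[length(rows) + 1L]] <- row("A", 242, "ARG", nm, argCoords[nm, ])
  for (nm in rownames(baseCoords))
    rows[[length(rows) + 1L]] <- row("B", 6, "DT", nm, baseCoords[nm, ],
                                     type = "HETATM")
  NeilTriage:::.newStructureModel("pair", do.call(rbind, rows))
}

## append water oxygens at given coordinates
addWaters <- function(model, coords) {
  row <- NeilTriage:::.atomRow
  rows <- lapply(seq_len(nrow(coords)), function(i) {
    r <- row("W", 2000L + i, "HOH", "O", coords[i, ], type = "HETATM")
    r$water <- TRUE
    r
  })
  NeilTriage:::.newStructureModel(model@identifier,
                                  rbind(model@atoms, do.call(rbind, rows)))
}
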
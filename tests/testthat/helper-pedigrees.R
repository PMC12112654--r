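# small reference pedigrees used across test files

ped_trio <- function() {
  pedigree(1, c("f", "m", "c"), c(0, 0, "f"), c(0, 0, "m"), c(1, 2, 1))
}

ped_nuclear <- function(nkids = 2) {
  kids <- paste0("k", seq_len(nkids))
  pedigree(1, c("f", "m", kids),
           c(0, 0, rep("f", nkids)), c(0, 0, rep("m", nkids)),
           c(1, 2, rep(1:2, length.out = nkids)))
}

# three generations: grandparents gf+gm; children c1 (with spouse s1) and c2;
# g1 = grandchild of gf/gm through c1; c2 is g1's aunt/uncle
ped_three_gen <- function() {
  pedigree(1,
           id     = c("gf", "gm", "c1", "s1", "c2", "g1"),
           father = c(0,    0,    "gf", 0,    "gf", "c1"),
           mother = c(0,    0,    "gm", 0,    "gm", "s1"),
           sex    = c(1, 2, 1, 2, 2, 1))
}

# half sibs (shared mother), plus first cousins through full sibs
ped_half_and_cousins <- function() {
  pedigree(1,
    id     = c("f1", "f2", "m",  "h1", "h2", "s1", "s2", "w1", "w2", "x1", "x2"),
    father = c(0,    0,    0,    "f1", "f2", "f1", "f1", 0,    0,    "s1", "s2"),
    mother = c(0,    0,    0,    "m",  "m",  "m",  "m",  0,    0,    "w1", "w2"),
    sex    = c(1, 1, 2, 1, 2, 1, 1, 2, 2, 1, 2))
}

# offspring of a full-sib mating (inbred), for the kinship recursion
ped_inbred <- function() {
  pedigree(1, c("f", "m", "s", "d", "x"),
           c(0, 0, "f", "f", "s"), c(0, 0, "m", "m", "d"),
           c(1, 2, 1, 2, 1))
}
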
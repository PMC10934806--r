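# Shared fixtures built in code at test time.

helix42 <- function() build_backbone(ab42_sequence(),
                                     dihedral_schedule("alpha", 42))

beta42 <- function() build_backbone(ab42_sequence(),
                                    dihedral_schedule("beta", 42))

# Minimal two-residue Ser-Asp system with an explicit sidechain
# donor/acceptor pair at controllable geometry, for hydrogen-bond
# detection tests. `d` is the donor-acceptor distance, `theta` the
# D-H...A angle in degrees.
hb_probe <- function(d = 2.9, theta = 180) {
  base <- build_backbone("SD", dihedral_schedule("beta", 2))
  top <- base$topology
  xyz <- get_frame(base, 1)
  A <- c(20, 0, 0)                     # acceptor OD1 (Asp2), far from chain
  D <- A + c(d, 0, 0)                  # donor OG (Ser1)
  # H 1.0 A from D such that angle(D, H, A) = theta
  ang <- (180 - theta) * pi / 180
  H <- D + c(-cos(ang), sin(ang), 0)
  extra <- data.frame(
    serial = 0L, name = c("OD1", "OG", "HG"),
    res_name = c("ASP", "SER", "SER"), chain_id = "A",
    res_seq = c(2L, 1L, 1L), element = c("O", "O", "H"),
    mass = c(15.999, 15.999, 1.008))
  top <- rbind(top, extra)
  top$serial <- seq_len(nrow(top))
  trajectory(top, rbind(xyz, A, D, H))
}

# Trajectory from a list of coordinate matrices over a fixed topology.
traj_from_frames <- function(template, frames) {
  trajectory(template$topology, frames)
}
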
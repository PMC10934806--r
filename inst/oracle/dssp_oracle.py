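#!/usr/bin/env python
"""Reference secondary-structure oracle.

Runs the MDAnalysis (pydssp-style) DSSP implementation on a PDB file and
prints one three-class label line ('H', 'E', '-') per model. Used only by
the test suite and the acceptance script as an implementation-independent
cross-check.
"""
import sys

import MDAnalysis as mda
from MDAnalysis.analysis.dssp import DSSP


def main(path):
    u = mda.Universe(path)
    res = DSSP(u, guess_hydrogens=True).run()
    for frame_labels in res.results.dssp:
        print("".join(frame_labels))


if __name__ == "__main__":
    main(sys.argv[1])
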
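"""Hashed Morgan count fingerprints (radius 2) for an id<TAB>smiles file.

Writes the package's sparse-pairs CSV. Approximates ECFC_4-style counts with
the open-source RDKit hashing; not bit-compatible with commercial pipelines.
"""
import sys

from rdkit import Chem
from rdkit.Chem import rdFingerprintGenerator


def main(inp, m, out):
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=m)
    rows = []
    with open(inp) as fh:
        for ln, line in enumerate(fh, 1):
            line = line.rstrip("\n")
            if not line.strip():
                continue
            try:
                mid, smi = line.split("\t")
            except ValueError:
                sys.exit(f"line {ln}: expected id<TAB>smiles")
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                sys.exit(f"line {ln}: unparsable SMILES {smi!r}")
            cnt = gen.GetCountFingerprint(mol).GetNonzeroElements()
            pairs = " ".join(f"{i}:{c}" for i, c in sorted(cnt.items()))
            rows.append(f"{mid},,{pairs}")
    with open(out, "w") as fh:
        fh.write("molecule_id,activity_class,features\n")
        fh.write("\n".join(rows) + ("\n" if rows else ""))


if __name__ == "__main__":
    main(sys.argv[1], int(sys.argv[2]), sys.argv[3])
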
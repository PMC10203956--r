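"""Batch chemistry backend.

Reads a JSON request from argv[1], writes a JSON response to argv[2].
All molecules are reduced to their largest fragment, stripped of
stereochemistry, and renumbered into RDKit's canonical atom ranking so that
atom indices are deterministic for a given structure regardless of the
input SMILES spelling.

Request format:
  {"op": <str>, ...op-specific fields...}

Ops:
  mol_info:      {"smiles": [..]}
  canonical:     {"smiles": [..]}
  ecfp:          {"smiles": [..], "n_bits": int, "radius": int}
  random_smiles: {"smiles": [..], "n": int, "seed": int}
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def sanitize_smiles(s):
    # the source tables print typographic spaces inside SMILES ("C2 = CC3")
    return "".join(s.split())


def std_mol(smiles):
    """Parse -> largest fragment -> strip stereo -> canonical atom order."""
    s = sanitize_smiles(smiles)
    if not s:
        return None
    mol = Chem.MolFromSmiles(s)
    if mol is None:
        return None
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    mol = max(frags, key=lambda f: f.GetNumHeavyAtoms())
    Chem.RemoveStereochemistry(mol)
    ranks = list(Chem.CanonicalRankAtoms(mol))
    order = [old for _, old in sorted(zip(ranks, range(mol.GetNumAtoms())))]
    return Chem.RenumberAtoms(mol, order)


def murcko_atoms(mol):
    scaffold = MurckoScaffold.GetScaffoldForMol(mol)
    n = scaffold.GetNumAtoms()
    if n == 0:
        return [], ""
    match = mol.GetSubstructMatch(scaffold)
    if len(match) != n:
        # extremely defensive: substructure match of a mol against its own
        # scaffold can in principle fail after sanitization differences
        match = mol.GetSubstructMatch(scaffold, useChirality=False)
    return sorted(match), Chem.MolToSmiles(scaffold)


def mol_info(smiles):
    mol = std_mol(smiles)
    if mol is None:
        return {"error": "SMILES parse error"}
    atoms = [
        {
            "element": a.GetSymbol(),
            "aromatic": a.GetIsAromatic(),
            "charge": a.GetFormalCharge(),
            "in_ring": a.IsInRing(),
            "degree": a.GetDegree(),
        }
        for a in mol.GetAtoms()
    ]
    bonds = [
        [b.GetBeginAtomIdx(), b.GetEndAtomIdx(), b.GetIsAromatic()]
        for b in mol.GetBonds()
    ]
    m_atoms, m_smiles = murcko_atoms(mol)
    return {
        "canonical_smiles": Chem.MolToSmiles(mol),
        "n_heavy": mol.GetNumHeavyAtoms(),
        "atoms": atoms,
        "bonds": bonds,
        "murcko_atoms": m_atoms,
        "murcko_smiles": m_smiles,
        "aromatic_atoms": [a.GetIdx() for a in mol.GetAtoms() if a.GetIsAromatic()],
    }


def run(req):
    op = req["op"]
    if op == "mol_info":
        return [mol_info(s) for s in req["smiles"]]
    if op == "canonical":
        out = []
        for s in req["smiles"]:
            mol = std_mol(s)
            out.append(None if mol is None else Chem.MolToSmiles(mol))
        return out
    if op == "ecfp":
        gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=int(req.get("radius", 2)), fpSize=int(req.get("n_bits", 1024))
        )
        out = []
        for s in req["smiles"]:
            mol = std_mol(s)
            if mol is None:
                out.append({"error": "SMILES parse error"})
            else:
                fp = gen.GetFingerprint(mol)
                out.append({"bits": list(fp.GetOnBits())})
        return out
    if op == "random_smiles":
        n = int(req.get("n", 10))
        seed = int(req.get("seed", 1))
        out = []
        for i, s in enumerate(req["smiles"]):
            mol = std_mol(s)
            if mol is None:
                out.append({"error": "SMILES parse error"})
            else:
                variants = Chem.MolToRandomSmilesVect(mol, n, randomSeed=seed + i)
                out.append({"smiles": list(variants)})
        return out
    raise ValueError("unknown op: %s" % op)


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    res = run(req)
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
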
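"""Structure preparation bridge.

Reads a JSON job description on argv[1], writes JSON results to argv[2].
Used by the R package for SMILES/SDF parsing, hydrogen addition, seeded
ETKDG 3D embedding, multi-conformer generation (RMSD-pruned), MMFF94
relative energies and Gasteiger partial charges. Everything downstream
(descriptors, screening, propensity model) lives in R.

Job schema:
  records: list of {name, smiles} or {name, molblock}
  n_confs: int (default 1)
  seed: int (default 1)
  prune_rms: float, heavy-atom RMSD pruning threshold in Angstrom (default 0.5)
  optimize: bool, MMFF-minimise conformers (default true)
  use_input_coords: bool, keep 3D coordinates found in molblocks (default true)

Each result record:
  name, smiles (canonical), natoms, nfrags
  atoms: {element, formal_charge, aromatic, partial_charge, in_ring}
  bonds: {i, j, order, aromatic}   (1-based indices)
  conformers: list of natoms x 3 coordinate lists
  energies: kcal/mol relative to the ensemble minimum (0.0 when not optimised)
  error: string (only on failure; other fields may be absent)
"""
import json
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def mol_payload(mol):
    atoms = {
        "element": [a.GetSymbol() for a in mol.GetAtoms()],
        "formal_charge": [a.GetFormalCharge() for a in mol.GetAtoms()],
        "aromatic": [bool(a.GetIsAromatic()) for a in mol.GetAtoms()],
        "in_ring": [bool(a.IsInRing()) for a in mol.GetAtoms()],
    }
    try:
        AllChem.ComputeGasteigerCharges(mol)
        charges = []
        for a in mol.GetAtoms():
            q = a.GetDoubleProp("_GasteigerCharge")
            charges.append(0.0 if q != q else round(q, 6))  # NaN guard
        atoms["partial_charge"] = charges
    except Exception:
        atoms["partial_charge"] = [0.0] * mol.GetNumAtoms()
    bonds = {
        "i": [b.GetBeginAtomIdx() + 1 for b in mol.GetBonds()],
        "j": [b.GetEndAtomIdx() + 1 for b in mol.GetBonds()],
        "order": [b.GetBondTypeAsDouble() for b in mol.GetBonds()],
        "aromatic": [bool(b.GetIsAromatic()) for b in mol.GetBonds()],
    }
    return atoms, bonds


def has_3d(mol):
    if mol.GetNumConformers() == 0:
        return False
    conf = mol.GetConformer()
    if not conf.Is3D():
        return False
    pos = conf.GetPositions()
    return float(abs(pos).sum()) > 1e-6


def embed(mol, n_confs, seed, prune_rms, optimize):
    n_confs = int(n_confs)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed) % (2**31 - 1)
    params.pruneRmsThresh = float(prune_rms)
    params.enforceChirality = True
    # over-sample embeddings: RMSD pruning discards near-duplicates, so ask
    # for more candidates than requested and keep the first n distinct ones
    n_try = n_confs if n_confs == 1 else n_confs * 4 + 8
    ids = AllChem.EmbedMultipleConfs(mol, numConfs=n_try, params=params)
    if len(ids) == 0:
        # fall back to random coordinates for pathological inputs
        params.useRandomCoords = True
        ids = AllChem.EmbedMultipleConfs(mol, numConfs=n_try, params=params)
    if len(ids) == 0:
        raise ValueError("3D embedding failed")
    for cid in list(ids)[n_confs:]:
        mol.RemoveConformer(cid)
    ids = [c.GetId() for c in mol.GetConformers()]
    energies = [0.0] * len(ids)
    if optimize and AllChem.MMFFHasAllMoleculeParams(mol):
        res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=2000)
        energies = [e for _, e in res]
    emin = min(energies)
    return ids, [round(e - emin, 6) for e in energies]


def process(rec, job):
    name = rec.get("name") or "unnamed"
    if "smiles" in rec:
        mol = Chem.MolFromSmiles(rec["smiles"])
        src3d = False
    else:
        mol = Chem.MolFromMolBlock(rec["molblock"], removeHs=False)
        src3d = mol is not None and has_3d(mol) and job.get("use_input_coords", True)
    if mol is None:
        return {"name": name, "error": "parse failure"}
    nfrags = len(Chem.GetMolFrags(mol))
    if nfrags > 1:
        return {"name": name, "error": "multi-fragment input", "nfrags": nfrags}
    mol = Chem.AddHs(mol, addCoords=src3d)
    smiles = Chem.MolToSmiles(Chem.RemoveHs(mol))
    n_confs = int(job.get("n_confs", 1))
    out = {"name": name, "smiles": smiles, "nfrags": 1,
           "natoms": mol.GetNumAtoms()}
    try:
        if src3d and n_confs == 1:
            energies = [0.0]
        else:
            _, energies = embed(mol, n_confs, job.get("seed", 1),
                                job.get("prune_rms", 0.5),
                                job.get("optimize", True))
    except ValueError as exc:
        return {"name": name, "error": str(exc)}
    atoms, bonds = mol_payload(mol)
    out["atoms"] = atoms
    out["bonds"] = bonds
    out["conformers"] = [
        [[round(v, 6) for v in conf.GetAtomPosition(i)]
         for i in range(mol.GetNumAtoms())]
        for conf in mol.GetConformers()
    ]
    out["energies"] = energies
    return out


def main():
    with open(sys.argv[1]) as fh:
        job = json.load(fh)
    results = [process(rec, job) for rec in job["records"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main()
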
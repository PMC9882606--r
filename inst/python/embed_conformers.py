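#!/usr/bin/env python
"""Conformer embedding helper.

Reads a molecule (SMILES or SDF), generates low-energy 3-D conformers by
seeded distance-geometry embedding (ETKDG) followed by MMFF94 minimization,
prunes near-duplicates by heavy-atom best-fit RMSD (keeping the lower-energy
member), and writes a multi-record SDF with explicit hydrogens. Each record
carries properties:
  energy          MMFF94 energy (kcal/mol)
  strain          energy above the best conformer
  aromatic_rings  semicolon-separated 1-based atom index lists

Modes:
  parse  validate/canonicalize input, print one JSON line, no embedding
  embed  write conformers SDF
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def load_molecule(args):
    if args.smiles is not None:
        mol = Chem.MolFromSmiles(args.smiles)
        if mol is None:
            raise ValueError("unparseable SMILES: %r" % args.smiles)
    else:
        supl = Chem.SDMolSupplier(args.sdf, removeHs=False)
        mols = [m for m in supl if m is not None]
        if not mols:
            raise ValueError("no parseable record in SDF: %s" % args.sdf)
        mol = mols[0]
    # salts: keep the largest fragment by heavy atom count
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) > 1:
        mol = max(frags, key=lambda f: f.GetNumHeavyAtoms())
    Chem.SanitizeMol(mol)
    return mol


def ring_property(mol):
    ri = mol.GetRingInfo()
    arom = []
    for ring in ri.AtomRings():
        if all(mol.GetAtomWithIdx(i).GetIsAromatic() for i in ring):
            arom.append(",".join(str(i + 1) for i in ring))
    return ";".join(arom)


def cmd_parse(args):
    mol = load_molecule(args)
    out = {
        "canonical_smiles": Chem.MolToSmiles(mol),
        "n_heavy_atoms": mol.GetNumHeavyAtoms(),
        "n_aromatic_rings": len([r for r in ring_property(mol).split(";") if r]),
        "n_rotatable_bonds": AllChem.CalcNumRotatableBonds(mol),
        "has_3d": mol.GetNumConformers() > 0 and mol.GetConformer().Is3D(),
    }
    json.dump(out, sys.stdout)
    sys.stdout.write("\n")


def cmd_embed(args):
    mol = load_molecule(args)
    molH = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = args.seed
    params.numThreads = 1
    n_embed = max(2 * args.n_max, 20)
    ids = AllChem.EmbedMultipleConfs(molH, numConfs=n_embed, params=params)
    if len(ids) == 0:
        raise ValueError("distance-geometry embedding failed for %s" % args.name)
    results = AllChem.MMFFOptimizeMoleculeConfs(molH, maxIters=1000)
    energies = {}
    for cid, (converged, energy) in zip(ids, results):
        if energy == -1:
            # no MMFF parameters: fall back to UFF
            ff_res = AllChem.UFFOptimizeMoleculeConfs(molH, maxIters=1000)
            energies = {c: e for c, (_, e) in zip(ids, ff_res)}
            break
        energies[cid] = energy

    order = sorted(ids, key=lambda c: (energies[c], c))
    heavy = Chem.RemoveHs(Chem.Mol(molH))
    kept = []
    for cid in order:
        dup = False
        for kid in kept:
            rms = AllChem.GetBestRMS(heavy, heavy, prbId=cid, refId=kid)
            if rms < args.rmsd_dedup:
                dup = True
                break
        if not dup:
            kept.append(cid)
        if len(kept) >= args.n_max:
            break

    rings = ring_property(molH)
    emin = min(energies[c] for c in kept)
    writer = Chem.SDWriter(args.out)
    writer.SetKekulize(True)
    molH.SetProp("_Name", args.name)
    for rank, cid in enumerate(kept):
        molH.SetProp("energy", "%.4f" % energies[cid])
        molH.SetProp("strain", "%.4f" % (energies[cid] - emin))
        molH.SetProp("conf_rank", str(rank + 1))
        molH.SetProp("aromatic_rings", rings)
        writer.write(molH, confId=cid)
    writer.close()
    json.dump({"n_conformers": len(kept)}, sys.stdout)
    sys.stdout.write("\n")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mode", choices=["parse", "embed"])
    ap.add_argument("--smiles")
    ap.add_argument("--sdf")
    ap.add_argument("--out")
    ap.add_argument("--name", default="mol")
    ap.add_argument("--n-max", type=int, default=200)
    ap.add_argument("--rmsd-dedup", type=float, default=0.5)
    ap.add_argument("--seed", type=int, default=1)
    args = ap.parse_args()
    if args.smiles is None and args.sdf is None:
        ap.error("one of --smiles or --sdf is required")
    try:
        if args.mode == "parse":
            cmd_parse(args)
        else:
            cmd_embed(args)
    except ValueError as exc:
        sys.stderr.write(str(exc) + "\n")
        sys.exit(2)


if __name__ == "__main__":
    main()
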
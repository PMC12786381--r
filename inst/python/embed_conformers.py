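#!/usr/bin/env python
"""Seeded 3D conformer generation: distance-geometry embedding followed
by MMFF94s minimization. Reads a TSV (id <tab> smiles) and writes an SDF
with energy_kcal_mol and smiles data fields; failures are reported on
stdout as 'FAIL<tab>id<tab>reason' and skipped.

Usage: embed_conformers.py input.tsv seed output.sdf
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("unparsable SMILES")
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    if AllChem.EmbedMolecule(mol, params) != 0:
        raise ValueError("distance-geometry embedding failed")
    try:
        AllChem.MMFFOptimizeMolecule(mol, mmffVariant="MMFF94s",
                                     maxIters=2000)
        props = AllChem.MMFFGetMoleculeProperties(mol,
                                                  mmffVariant="MMFF94s")
        ff = AllChem.MMFFGetMoleculeForceField(mol, props)
        energy = ff.CalcEnergy()
    except Exception:
        # atoms outside MMFF coverage: minimize with UFF, no energy
        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
        energy = float("nan")
    return mol, energy


def main(argv):
    inp, seed, out = argv[1], int(argv[2]), argv[3]
    writer = Chem.SDWriter(out)
    writer.SetKekulize(True)
    with open(inp) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            mid, smiles = line.split("\t")[:2]
            try:
                mol, energy = embed(smiles, seed)
            except Exception as exc:  # reported, not fatal
                print("FAIL\t%s\t%s" % (mid, exc))
                continue
            mol.SetProp("_Name", mid)
            mol.SetProp("energy_kcal_mol", repr(energy))
            mol.SetProp("smiles", smiles)
            writer.write(mol)
    writer.close()


if __name__ == "__main__":
    main(sys.argv)
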
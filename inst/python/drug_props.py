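"""Descriptor helper: QED, SA score, Crippen logP and Lipinski counts.

Reads one molecule (--sdf file or --smiles string), prints one JSON
object on stdout. Unsanitizable input yields {"valid": false} with exit
status 0 so the caller can flag-and-continue.
"""
import argparse
import json
import os
import sys


def main():
    ap = argparse.ArgumentParser()
    g = ap.add_mutually_exclusive_group(required=True)
    g.add_argument("--sdf")
    g.add_argument("--smiles")
    args = ap.parse_args()

    from rdkit import Chem, RDLogger
    from rdkit.Chem import Crippen, Descriptors, QED, RDConfig, rdMolDescriptors

    RDLogger.DisableLog("rdApp.*")
    sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer

    if args.smiles:
        mol = Chem.MolFromSmiles(args.smiles)
    else:
        supp = Chem.SDMolSupplier(args.sdf, removeHs=False, sanitize=True)
        mol = supp[0] if len(supp) else None
    if mol is None:
        print(json.dumps({"valid": False}))
        return
    try:
        Chem.SanitizeMol(mol)
        out = {
            "valid": True,
            "qed": QED.qed(mol),
            "sa": sascorer.calculateScore(mol),
            "logp": Crippen.MolLogP(mol),
            "mw": Descriptors.MolWt(mol),
            "hbd": rdMolDescriptors.CalcNumHBD(mol),
            "hba": rdMolDescriptors.CalcNumHBA(mol),
            "rotb": rdMolDescriptors.CalcNumRotatableBonds(mol),
        }
    except Exception:
        out = {"valid": False}
    print(json.dumps(out))


if __name__ == "__main__":
    main()
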
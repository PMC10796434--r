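"""Physicochemical descriptors via RDKit.

Usage: python descriptors.py in.csv out.csv
in.csv: drug_id,smiles ; out.csv adds logp,hbd,hba,qed,status,backend.
"""
import csv
import sys

from rdkit import Chem, rdBase
from rdkit.Chem import Crippen, Lipinski, QED
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main(infile, outfile):
    backend = f"rdkit-{rdBase.rdkitVersion}"
    with open(infile) as fh:
        rows = list(csv.DictReader(fh))
    out = []
    for row in rows:
        mol = Chem.MolFromSmiles(row["smiles"])
        if mol is None:
            out.append({"drug_id": row["drug_id"], "logp": "", "hbd": "",
                        "hba": "", "qed": "", "status": "parse_error",
                        "backend": backend})
            continue
        out.append({
            "drug_id": row["drug_id"],
            "logp": repr(Crippen.MolLogP(mol)),
            "hbd": Lipinski.NumHDonors(mol),
            "hba": Lipinski.NumHAcceptors(mol),
            "qed": repr(QED.qed(mol)),
            "status": "ok",
            "backend": backend,
        })
    with open(outfile, "w", newline="") as fh:
        w = csv.DictWriter(fh, fieldnames=["drug_id", "logp", "hbd", "hba",
                                           "qed", "status", "backend"])
        w.writeheader()
        w.writerows(out)


if __name__ == "__main__":
    main(*sys.argv[1:3])
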
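"""Batch fit/predict bridge.

Usage: python sklearn_bridge.py X.csv jobs.json out.csv

X.csv: headerless numeric feature matrix covering every referenced row.
jobs.json: {family, params, class_weight, jobs: [{id, seed, train, test, y}]}
           with 0-based row indices.
out.csv: job_id,row,prob  (row is the 0-based index into X of a test row;
         prob is the positive-class probability).
"""
import json
import sys

import numpy as np


def make_model(family, params, class_weight, seed):
    p = dict(params)
    if family == "LR":
        from sklearn.linear_model import LogisticRegression
        return LogisticRegression(
            penalty=p.get("penalty", "l2"), tol=p.get("tol", 1e-4),
            C=p.get("C", 0.45), max_iter=int(p.get("max_iter", 500)),
            class_weight=class_weight, random_state=seed)
    if family == "SVM":
        from sklearn.svm import SVC
        return SVC(
            C=p.get("C", 0.42), kernel=p.get("kernel", "linear"),
            tol=p.get("tol", 1e-3), probability=bool(p.get("probability", True)),
            class_weight=class_weight, random_state=seed)
    if family == "RF":
        from sklearn.ensemble import RandomForestClassifier
        return RandomForestClassifier(
            n_estimators=int(p.get("n_estimators", 300)),
            min_samples_leaf=int(p.get("min_samples_leaf", 85)),
            max_features=p.get("max_features", "sqrt"),
            class_weight=class_weight, random_state=seed, n_jobs=1)
    if family == "GBT":
        from sklearn.ensemble import GradientBoostingClassifier
        return GradientBoostingClassifier(
            n_estimators=int(p.get("n_estimators", 650)),
            min_samples_leaf=int(p.get("min_samples_leaf", 120)),
            max_features=p.get("max_features", "sqrt"),
            learning_rate=p.get("learning_rate", 0.28),
            max_depth=int(p.get("max_depth", 5)),
            random_state=seed)
    raise ValueError(f"unknown model family: {family}")


def main(xfile, jfile, ofile):
    X = np.loadtxt(xfile, delimiter=",", ndmin=2)
    with open(jfile) as fh:
        spec = json.load(fh)
    class_weight = spec.get("class_weight")
    lines = ["job_id,row,prob"]
    for job in spec["jobs"]:
        train = np.asarray(job["train"], dtype=int)
        test = np.asarray(job["test"], dtype=int)
        y = np.asarray(job["y"], dtype=int)
        model = make_model(spec["family"], spec.get("params", {}),
                           class_weight, int(job["seed"]))
        model.fit(X[train], y)
        if len(model.classes_) == 1:
            prob = np.full(len(test), float(model.classes_[0]))
        else:
            pos = int(np.where(model.classes_ == 1)[0][0])
            prob = model.predict_proba(X[test])[:, pos]
        for row, pr in zip(test, prob):
            lines.append(f"{job['id']},{row},{float(pr)!r}")
    with open(ofile, "w") as fh:
        fh.write("\n".join(lines) + "\n")


if __name__ == "__main__":
    main(*sys.argv[1:4])
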
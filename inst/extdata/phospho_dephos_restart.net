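node Start kind=core theta=0 selfdeg=1 clamp=none init=1
node Cig1/Cdc2 kind=core theta=0 selfdeg=1 clamp=none init=0
node Cig2/Cdc2 kind=core theta=0 selfdeg=1 clamp=none init=0
node Puc1/Cdc2 kind=core theta=0 selfdeg=1 clamp=none init=0
node Cdc2/Cdc13 kind=core theta=-0.5 selfdeg=0 clamp=none init=0
node Ste9 kind=core theta=0 selfdeg=0 clamp=none init=1
node Rum1 kind=core theta=0 selfdeg=0 clamp=none init=1
node Slp1 kind=core theta=0 selfdeg=1 clamp=none init=0
node Cdc2_Tyr15 kind=core theta=0 selfdeg=0 clamp=none init=0
node Wee1/Mik1 kind=core theta=0 selfdeg=0 clamp=none init=1
node Cdc25 kind=core theta=0 selfdeg=0 clamp=none init=0
node PP kind=core theta=0 selfdeg=1 clamp=none init=0
node Sep1 kind=substrate theta=0 selfdeg=0 clamp=none init=0
node Fkh2 kind=substrate theta=0 selfdeg=0 clamp=none init=1
node Atf1 kind=substrate theta=0 selfdeg=0 clamp=none init=0
node Cdc10 kind=substrate theta=0 selfdeg=0 clamp=1 init=1
pattern row1 {Start=1, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=0, Ste9=1, Rum1=1, Slp1=0, Cdc2_Tyr15=0, Wee1/Mik1=1, Cdc25=0, PP=0} label="Start"
pattern row2 {Start=0, Cig1/Cdc2=1, Cig2/Cdc2=1, Puc1/Cdc2=1, Cdc2/Cdc13=0, Ste9=1, Rum1=1, Slp1=0, Cdc2_Tyr15=0, Wee1/Mik1=1, Cdc25=0, PP=0} label="G1"
pattern row3 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=0, Ste9=0, Rum1=0, Slp1=0, Cdc2_Tyr15=0, Wee1/Mik1=1, Cdc25=0, PP=0} label="G1/S"
pattern row4 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=1, Ste9=0, Rum1=0, Slp1=0, Cdc2_Tyr15=0, Wee1/Mik1=1, Cdc25=0, PP=0} label="G2"
pattern row5 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=1, Ste9=0, Rum1=0, Slp1=0, Cdc2_Tyr15=0, Wee1/Mik1=0, Cdc25=1, PP=0} label="G2"
pattern row6 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=1, Ste9=0, Rum1=0, Slp1=0, Cdc2_Tyr15=1, Wee1/Mik1=0, Cdc25=1, PP=0} label="G2/M"
pattern row7 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=1, Ste9=0, Rum1=0, Slp1=1, Cdc2_Tyr15=1, Wee1/Mik1=0, Cdc25=1, PP=0} label="G2/M"
pattern row8 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=0, Ste9=0, Rum1=0, Slp1=1, Cdc2_Tyr15=1, Wee1/Mik1=0, Cdc25=1, PP=1} label="M"
pattern row9 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=0, Ste9=1, Rum1=1, Slp1=0, Cdc2_Tyr15=1, Wee1/Mik1=1, Cdc25=0, PP=1} label="M"
pattern row10 {Start=0, Cig1/Cdc2=0, Cig2/Cdc2=0, Puc1/Cdc2=0, Cdc2/Cdc13=0, Ste9=1, Rum1=1, Slp1=0, Cdc2_Tyr15=0, Wee1/Mik1=1, Cdc25=0, PP=0} label="G1"
pattern sep1_active {Sep1=1} label="Sep1 active"
pattern fkh2_active {Fkh2=1} label="Fkh2 active"
edge Start -> Cig1/Cdc2 sign=+ gate=none
edge Start -> Cig2/Cdc2 sign=+ gate=none
edge Start -> Puc1/Cdc2 sign=+ gate=none
edge Cig1/Cdc2 -> Ste9 sign=- gate=none
edge Cig1/Cdc2 -> Rum1 sign=- gate=none
edge Cig2/Cdc2 -> Ste9 sign=- gate=none
edge Cig2/Cdc2 -> Rum1 sign=- gate=none
edge Puc1/Cdc2 -> Ste9 sign=- gate=none
edge Puc1/Cdc2 -> Rum1 sign=- gate=none
edge Ste9 -> Cdc2/Cdc13 sign=- gate=none
edge Rum1 -> Cdc2/Cdc13 sign=- gate=none
edge Slp1 -> Cdc2/Cdc13 sign=- gate=none
edge Cdc2/Cdc13 -> Ste9 sign=- gate=none
edge Cdc2/Cdc13 -> Rum1 sign=- gate=none
edge Cdc2/Cdc13 -> Wee1/Mik1 sign=- gate=none
edge Cdc2/Cdc13 -> Cdc25 sign=+ gate=none
edge PP -> Ste9 sign=+ gate=none
edge PP -> Rum1 sign=+ gate=none
edge PP -> Wee1/Mik1 sign=+ gate=none
edge PP -> Cdc25 sign=- gate=none
edge PP -> Slp1 sign=- gate=none
edge Cdc2_Tyr15 -> Slp1 sign=+ gate=none
edge Cdc25 -> Cdc2_Tyr15 sign=+ gate=none
edge Wee1/Mik1 -> Cdc2_Tyr15 sign=- gate=none
edge Slp1 -> PP sign=+ gate=none
edge Atf1 -> Cdc2/Cdc13 sign=+ gate=row6
event phos_Sep1 priority=10 trigger=row5 when=none set {Sep1=1}
event phos_Atf1 priority=11 trigger=row5 when=none set {Atf1=1}
event phos_Fkh2 priority=12 trigger=row2 when=none set {Fkh2=0}
event Rum1_by_Sep1_Fkh2 priority=13 trigger=row7 when=sep1_active,fkh2_active set {Rum1=1}
event dephos_Fkh2_S priority=20 trigger=row4 when=none set {Fkh2=1}
event dephos_mitotic_exit priority=21 trigger=row10 when=none set {Sep1=0, Atf1=0}
event restart_by_Cdc10 priority=30 trigger=row9 when=none set {Start=1, Sep1=0, Atf1=0}
phase row1 "Start"
phase row2 "G1"
phase row3 "G1/S"
phase row4 "G2"
phase row5 "G2"
phase row6 "G2/M"
phase row7 "G2/M"
phase row8 "M"
phase row9 "M"
phase row10 "G1"
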
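angry	-0.7	anger
furious	-0.8	anger
rage	-0.8	anger
annoyed	-0.5	anger
irritated	-0.5	anger
mad	-0.6	anger
resentful	-0.6	anger
hostile	-0.7	anger
outraged	-0.7	anger
frustrated	-0.5	anger
bitter	-0.5	anger
fuming	-0.7	anger
disgusted	-0.7	disgust
gross	-0.6	disgust
revolting	-0.8	disgust
nasty	-0.6	disgust
repulsed	-0.7	disgust
sickening	-0.7	disgust
vile	-0.8	disgust
foul	-0.6	disgust
yuck	-0.5	disgust
loathing	-0.7	disgust
distaste	-0.5	disgust
queasy	-0.4	disgust
afraid	-0.6	fear
scared	-0.6	fear
anxious	-0.5	fear
terrified	-0.8	fear
nervous	-0.4	fear
worried	-0.5	fear
panic	-0.7	fear
dread	-0.7	fear
frightened	-0.6	fear
uneasy	-0.4	fear
apprehensive	-0.4	fear
fearful	-0.6	fear
happy	0.6	joy
joyful	0.8	joy
delighted	0.8	joy
cheerful	0.7	joy
glad	0.6	joy
excited	0.7	joy
thrilled	0.8	joy
hopeful	0.6	joy
grateful	0.7	joy
proud	0.7	joy
wonderful	0.8	joy
upbeat	0.6	joy
sad	-0.6	sadness
unhappy	-0.6	sadness
depressed	-0.8	sadness
miserable	-0.8	sadness
gloomy	-0.6	sadness
tearful	-0.6	sadness
lonely	-0.6	sadness
hopeless	-0.8	sadness
grief	-0.8	sadness
sorrow	-0.7	sadness
heartbroken	-0.8	sadness
downhearted	-0.6	sadness
good	0.5	
great	0.7	
love	0.8	
awesome	0.8	
nice	0.5	
amazing	0.8	
fantastic	0.8	
enjoy	0.6	
enjoyed	0.6	
better	0.4	
positive	0.5	
success	0.6	
calm	0.5	
relaxed	0.5	
confident	0.6	
strong	0.5	
bad	-0.5	
terrible	-0.8	
awful	-0.8	
horrible	-0.8	
hate	-0.8	
worse	-0.5	
stress	-0.5	
stressed	-0.5	
fail	-0.6	
failed	-0.6	
tired	-0.4	
hurt	-0.6	
struggle	-0.5	
struggling	-0.5	
pain	-0.6	
worst	-0.8	
work	0	
job	0	
school	0	
exam	0	
exams	0	
study	0	
sleep	0	
friend	0	
friends	0	
family	0	
home	0	
today	0	
week	0	
music	0	
walk	0	
food	0	
weather	0	
game	0	
book	0	
phone	0	
talk	0	
plan	0	
team	0	
project	0	
money	0	
health	0	
exercise	0	
morning	0	
evening	0	
people	0	
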
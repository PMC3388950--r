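facility_type,met,source_note
athletics track,8.0,running hard training typical use
badminton court,4.5,badminton social singles and doubles
ballistics hall,2.5,pistol shooting standing
basketball court,6.0,basketball non-game general
bowling green,3.0,lawn bowling outdoor
boxing club,7.8,boxing sparring
climbing wall,7.5,rock climbing ascending
cricket square,5.0,cricket batting bowling
croquet lawn,2.5,croquet
curling rink,4.0,curling
cycle track,8.0,cycling training
dance studio,4.8,general dancing
equestrian centre,4.0,horseback riding general
fitness suite,5.5,health club exercise general
five a side pitch,7.0,soccer casual small sided
football pitch,7.0,soccer casual general
gaelic football pitch,8.0,gaelic football typically vigorous
golf course,4.3,golf walking carrying clubs
golf driving range,3.0,golf driving range practice
gymnasium,5.5,gymnastics and circuit general
gymnastics centre,5.5,gymnastics general
hockey pitch,7.8,field hockey
ice rink,7.0,ice skating general
indoor bowling centre,3.0,bowling indoor carpet
indoor small bore rifle range,2.5,rifle shooting standing
indoor tennis centre,5.0,tennis doubles
judo hall,10.0,martial arts judo
lacrosse pitch,8.0,lacrosse
netball court,6.0,netball general play
pistol shooting range,2.5,pistol shooting standing
pitch and putt course,4.3,golf short course walking
rowing club,7.0,rowing moderate effort
rugby pitch,8.3,rugby competitive
running track,8.0,running training
shinty pitch,8.0,shinty typically vigorous
skate park,5.0,skateboarding general
ski slope,7.0,skiing downhill vigorous effort
sports hall,5.0,mixed indoor court sports
squash court,7.3,squash general
swimming pool,7.0,swimming laps freestyle moderate
table tennis hall,4.0,table tennis
tennis court,5.0,tennis doubles
velodrome,8.5,cycling track
water sports centre,5.0,canoeing and sailing mixed
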